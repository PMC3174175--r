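#' @include accumulation.R
NULL

#' Protein concentration series container
#'
#' A thin constructor validating the contract used throughout: strictly
#' increasing times in minutes, strictly positive concentrations in
#' arbitrary units.
#'
#' @param time_min numeric, strictly increasing.
#' @param concentration numeric, > 0.
#' @param protein product identifier.
#' @return data.frame with attribute \code{protein}.
#' @export
proteinSeries <- function(time_min, concentration, protein = "protein") {
  stopifnot(length(time_min) == length(concentration), length(time_min) >= 2)
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing")
  if (any(concentration <= 0)) stop("concentrations must be positive")
  out <- data.frame(time_min = time_min, concentration = concentration)
  attr(out, "protein") <- protein
  out
}

#' Mean transition duration from the N-end rule
#'
#' One chain iteration applies the passive factor \code{rho}; the shortest
#' amino-acid half-life \code{halfLife} (minutes) of the protein of
#' interest therefore corresponds to \code{log(1/2)/log(rho)} iterations,
#' giving a per-iteration duration of
#' \code{halfLife * log(1/rho) / log(2)} minutes.
#'
#' @param rho passive rate, in (0, 1).
#' @param halfLife shortest amino-acid half-life, minutes.
#' @return mean duration of one transition, minutes.
#' @examples
#' transitionDuration(0.5, 2)   # one step halves: delta = half-life
#' @export
transitionDuration <- function(rho, halfLife) {
  stopifnot(halfLife > 0, rho > 0)
  if (rho >= 1) stop("rho = 1: passive decay never halves, duration undefined")
  halfLife * log(1 / rho) / log(2)
}

#' Fit a succession of exponential laws to a protein series
#'
#' Within each segment delimited by the cutpoints the concentration is
#' modeled as \code{K * f^(t - t_start)} with a per-minute growth factor
#' \code{f}. Segments with more than two points are fitted by least
#' squares on log-concentration; segments with exactly two points use the
#' endpoint ratio (the sparse-data case). The basal level defaults to
#' zero; a positive basal switches to an iterative nonlinear fit of
#' \code{basal + K * f^t}.
#'
#' @param series a \code{\link{proteinSeries}} data.frame.
#' @param cutpoints full segment boundaries in minutes, starting at the
#'   first time and ending at the last (e.g. \code{c(0, 80, 140)} for two
#'   segments); boundary points belong to both adjacent segments.
#' @param basal basal concentration (default 0).
#' @return list of class \code{"piecewiseExpFit"}: per-segment
#'   \code{t_start}, \code{t_end}, \code{K} (initial value), \code{factor}
#'   (per-minute), \code{logResidual}; plus \code{basal}, \code{protein}.
#' @export
fitPiecewiseExponential <- function(series, cutpoints = NULL, basal = 0) {
  t <- series$time_min; c_ <- series$concentration
  if (any(c_ <= 0)) stop("nonpositive concentration")
  if (is.null(cutpoints)) cutpoints <- range(t)
  stopifnot(length(cutpoints) >= 2, !is.unsorted(cutpoints, strictly = TRUE))
  segs <- vector("list", length(cutpoints) - 1)
  for (i in seq_along(segs)) {
    lo <- cutpoints[i]; hi <- cutpoints[i + 1]
    in_seg <- t >= lo - 1e-9 & t <= hi + 1e-9
    if (sum(in_seg) < 2)
      stop(sprintf("segment [%g, %g] contains fewer than 2 points", lo, hi))
    ts <- t[in_seg] - lo; cs <- c_[in_seg]
    if (basal > 0) {
      if (any(cs <= basal)) stop("concentrations must exceed the basal level")
      fit0 <- stats::lm(log(cs - basal) ~ ts)
      par <- stats::optim(c(log(exp(coef(fit0)[1])), coef(fit0)[2]),
        function(p) sum((log(cs) - log(basal + exp(p[1]) * exp(p[2] * ts)))^2),
        method = "BFGS")
      K <- exp(par$par[1]); f <- exp(par$par[2]); res <- par$value
    } else if (sum(in_seg) == 2) {
      K <- cs[1]
      f <- (cs[2] / cs[1])^(1 / (ts[2] - ts[1]))
      res <- 0
    } else {
      fit <- stats::lm(log(cs) ~ ts)
      K <- exp(unname(coef(fit)[1]))
      f <- exp(unname(coef(fit)[2]))
      res <- sum(stats::residuals(fit)^2)
    }
    segs[[i]] <- list(t_start = lo, t_end = hi, K = K, factor = f,
                      logResidual = res)
  }
  structure(list(segments = segs, basal = basal,
                 protein = attr(series, "protein")),
            class = "piecewiseExpFit")
}

#' @export
print.piecewiseExpFit <- function(x, ...) {
  cat(sprintf("Piecewise exponential fit ('%s'), %d segment(s), basal %g\n",
              x$protein %||% "?", length(x$segments), x$basal))
  for (s in x$segments)
    cat(sprintf("  [%g, %g] min: K = %.4g, factor = %.6g / min\n",
                s$t_start, s$t_end, s$K, s$factor))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-transition growth objective from a fitted segment
#'
#' In the permanent regime the accumulated cost grows by the Perron
#' eigenvalue \code{lambda} per chain iteration, so an observed exponential
#' segment with per-minute factor \code{f} and mean transition duration
#' \code{delta} minutes pins \code{lambda = f^delta} (equivalently
#' \code{lambda^(dt/delta)} equals the concentration ratio over the
#' segment).
#'
#' @param fit a \code{\link{fitPiecewiseExponential}} result.
#' @param segment segment index.
#' @param delta mean transition duration, minutes (see
#'   \code{\link{transitionDuration}}).
#' @param width optional half-width of a relative validity interval:
#'   \code{width = 0.05} yields \code{[0.95, 1.05] * lambda}. Default 0
#'   (exact objective).
#' @return list of class \code{"growthObjective"} with \code{protein},
#'   \code{segment}, \code{lambda}, \code{lo}, \code{hi}, \code{delta}.
#' @export
growthObjective <- function(fit, segment = 1, delta, width = 0) {
  stopifnot(delta > 0, width >= 0, segment >= 1,
            segment <= length(fit$segments))
  sg <- fit$segments[[segment]]
  if (sg$t_end <= sg$t_start) stop("zero-duration segment")
  lambda <- sg$factor^delta
  structure(list(protein = fit$protein, segment = segment, lambda = lambda,
                 lo = lambda * (1 - width), hi = lambda * (1 + width),
                 delta = delta),
            class = "growthObjective")
}

#' Reconstruct a concentration curve from per-segment growth factors
#'
#' Inverse of \code{\link{growthObjective}}: builds the continuous
#' piecewise exponential \code{c(t) = K_seg * lambda^((t - t_seg)/delta)}
#' with segment boundaries at the cutpoints.
#'
#' @param lambdas per-transition growth factor, one per segment.
#' @param delta mean transition duration, minutes.
#' @param K0 initial concentration.
#' @param times evaluation times, minutes.
#' @param cutpoints segment boundaries (defaults to a single segment
#'   spanning \code{times}).
#' @param protein identifier for the returned series.
#' @return a \code{\link{proteinSeries}} data.frame.
#' @export
reconstructSeries <- function(lambdas, delta, K0, times, cutpoints = NULL,
                              protein = "protein") {
  stopifnot(all(lambdas > 0), delta > 0, K0 > 0)
  if (is.null(cutpoints)) cutpoints <- range(times)
  stopifnot(length(lambdas) == length(cutpoints) - 1)
  K <- K0
  conc <- numeric(length(times))
  for (i in seq_along(lambdas)) {
    lo <- cutpoints[i]; hi <- cutpoints[i + 1]
    sel <- times >= lo - 1e-9 & (times < hi | i == length(lambdas))
    conc[sel] <- K * lambdas[i]^((times[sel] - lo) / delta)
    K <- K * lambdas[i]^((hi - lo) / delta)
  }
  proteinSeries(times, conc, protein)
}

#' Pearson comparison of two concentration series
#'
#' Resamples \code{b} onto the time grid of \code{a} by exponential
#' (log-linear) interpolation, then reports the Pearson correlation and
#' its test p-value on the common grid.
#'
#' @param a,b \code{\link{proteinSeries}} data.frames.
#' @return list with \code{r}, \code{p.value}, \code{n}.
#' @export
compareSeries <- function(a, b) {
  tcommon <- a$time_min[a$time_min >= min(b$time_min) - 1e-9 &
                        a$time_min <= max(b$time_min) + 1e-9]
  if (length(tcommon) < 3) stop("fewer than 3 common time points")
  bi <- exp(stats::approx(b$time_min, log(b$concentration),
                          xout = tcommon, rule = 2)$y)
  ai <- a$concentration[match(tcommon, a$time_min)]
  ct <- suppressWarnings(stats::cor.test(ai, bi))
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(tcommon))
}
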