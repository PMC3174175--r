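#' @include timeseries.R
NULL

#' Growth-rate objective for reverse engineering
#'
#' Pairs a per-protein impact matrix with a target Perron eigenvalue (or a
#' validity interval). A set of such objectives — possibly spanning
#' several proteins and environmental phases — defines the inference
#' problem: find row-stochastic matrices on the ETG support whose cost
#' matrices achieve the targets.
#'
#' @param impact an \linkS4class{ImpactMatrix} built on the (phase-
#'   restricted) graph the objective refers to.
#' @param lambda target growth factor per transition; ignored when
#'   \code{lo}/\code{hi} are given.
#' @param lo,hi optional interval bounds (\code{lo = hi = lambda} gives an
#'   exact objective).
#' @param condition optional condition label of the phase; evaluation then
#'   restricts a candidate matrix to that phase's edge set (probabilities
#'   shared on common edges, removed rows renormalized).
#' @param aTarget optional target for the permanent-regime constant
#'   \code{a} of the accumulation rule (the initial-condition fit of the
#'   asymptotic mean law \code{mean(n) ~ a * lambda^n} from the uniform
#'   initial distribution). When given, the inference score also
#'   penalizes \code{|a - aTarget|}; by default only the growth rate is
#'   scored.
#' @return list of class \code{"etmcObjective"}.
#' @export
objective <- function(impact, lambda = NULL, lo = NULL, hi = NULL,
                      condition = NULL, aTarget = NULL) {
  if (is.null(lo) != is.null(hi)) stop("give both lo and hi, or neither")
  if (is.null(lo)) { lo <- lambda; hi <- lambda }
  if (is.null(lambda)) lambda <- (lo + hi) / 2
  stopifnot(lambda > 0, lo <= hi)
  structure(list(impact = impact, lambda = lambda, lo = lo, hi = hi,
                 condition = condition, aTarget = aTarget),
            class = "etmcObjective")
}

# evaluate achieved growth rates (and, when targeted, a-constants) of P
.achieved <- function(P, objectives, etg = NULL) {
  lam <- numeric(length(objectives))
  acon <- rep(NA_real_, length(objectives))
  for (k in seq_along(objectives)) {
    ob <- objectives[[k]]
    Pk <- P
    if (!is.null(ob$condition)) {
      if (is.null(etg)) stop("phase objectives require the full graph")
      Pk <- restrictRenormalize(P, etg, condition = ob$condition)
    }
    if (!identical(dim(Pk@values), dim(ob$impact@values)))
      stop("objective impact matrix does not match the (restricted) support")
    cv <- Pk@values * ob$impact@values
    if (is.null(ob$aTarget)) {
      lam[k] <- .perron_radius(cv)
    } else {
      de <- .perron_vectors(cv)
      lam[k] <- de$lambda
      # a = (v0 . right)(left . 1) for uniform v0; sum(right) = 1
      acon[k] <- sum(de$left) / length(de$left)
    }
  }
  list(lambdas = lam, a = acon)
}

.achieved_lambdas <- function(P, objectives, etg = NULL) {
  .achieved(P, objectives, etg)$lambdas
}

#' Inference score of a transition matrix
#'
#' Euclidean distance between the vector of achieved growth rates (Perron
#' eigenvalues of the per-objective cost matrices) and the objective
#' values (interval midpoints for interval objectives).
#'
#' @param P a \linkS4class{TransitionMatrix}.
#' @param objectives list of \code{\link{objective}}s.
#' @param etg full graph (needed only for phase-conditional objectives).
#' @return nonnegative scalar.
#' @export
scoreChain <- function(P, objectives, etg = NULL) {
  ach <- .achieved(P, objectives, etg)
  tgt <- vapply(objectives, `[[`, 0, "lambda")
  res <- ach$lambdas - tgt
  at <- vapply(objectives, function(o) o$aTarget %||% NA_real_, 0)
  has_a <- !is.na(at)
  if (any(has_a)) res <- c(res, ach$a[has_a] - at[has_a])
  sqrt(sum(res^2))
}

## ---- free-parameter coordinates -------------------------------------------
## One coordinate per supported edge except the last of each free row; the
## last edge carries the residual mass. Rows with out-degree 1 (or excluded
## from freeRows) are fixed and carry no coordinate.

.coord_map <- function(etg, freeRows = NULL, reference = NULL) {
  s <- .support_matrix(etg)
  lab <- rownames(s)
  if (is.null(reference)) reference <- uniformChain(etg)
  if (is.null(freeRows)) freeRows <- lab[rowSums(s) >= 2]
  freeRows <- intersect(freeRows, lab[rowSums(s) >= 2])
  coords <- list()
  for (r in freeRows) {
    out <- which(s[r, ])
    coords[[r]] <- out[-length(out)]  # last out-edge = residual
  }
  dims <- unlist(lapply(names(coords), function(r)
    paste0(r, "->", lab[coords[[r]]])), use.names = FALSE)
  list(support = s, labels = lab, free = coords, dim = length(dims),
       dimnames = dims, reference = reference@values)
}

.coords_of <- function(map, P) {
  v <- if (is(P, "TransitionMatrix")) P@values else P
  unlist(lapply(names(map$free), function(r) v[r, map$free[[r]]]),
         use.names = FALSE)
}

.matrix_of <- function(map, x) {
  v <- map$reference
  i <- 1
  for (r in names(map$free)) {
    cols <- map$free[[r]]
    k <- length(cols)
    v[r, ] <- 0
    v[r, cols] <- x[i:(i + k - 1)]
    out <- which(map$support[r, ])
    last <- out[length(out)]
    v[r, last] <- 1 - sum(x[i:(i + k - 1)])
    i <- i + k
  }
  v
}

.coords_feasible <- function(map, x, tol = 0) {
  if (any(x < -tol)) return(FALSE)
  i <- 1
  for (r in names(map$free)) {
    k <- length(map$free[[r]])
    if (sum(x[i:(i + k - 1)]) > 1 + tol) return(FALSE)
    i <- i + k
  }
  TRUE
}

.tm_from_coords <- function(map, x) {
  new("TransitionMatrix", values = .matrix_of(map, x), support = map$support)
}

# score in coordinate space; +Inf outside the simplex or on broken supports
.coord_score <- function(map, x, objectives, etg) {
  if (!.coords_feasible(map, x, tol = 1e-12)) return(Inf)
  P <- .tm_from_coords(map, pmax(x, 0))
  tryCatch(scoreChain(P, objectives, etg), error = function(e) Inf)
}

#' Ad-hoc local search for a matrix matching growth objectives
#'
#' Multi-start adaptive coordinate search on the free-parameter space (one
#' probability coordinate per supported edge minus one per row). Starting
#' from the uniform chain plus seeded random restarts, each move perturbs
#' one coordinate (one row of the simplex) and re-evaluates the Perron
#' eigenvalues numerically; the step size is halved whenever a full sweep
#' brings no improvement. Each start is then polished by a derivative-free
#' simplex descent on the same implicit-eigenvalue score. Deterministic
#' given \code{seed}.
#'
#' @param etg the \linkS4class{EventTransitionGraph} (full graph; phase
#'   objectives restrict it internally).
#' @param objectives list of \code{\link{objective}}s (nonempty).
#' @param seed RNG seed.
#' @param tol stop when the score drops below this (default 1e-6).
#' @param maxEval evaluation budget over all starts (default 20000).
#' @param nStarts number of starts (default 8; the first is the uniform
#'   chain).
#' @param freeRows optional event labels whose rows are searched; other
#'   rows stay at the uniform reference (used by the two-gene tutorial,
#'   whose printed matrix has exactly two unknowns).
#' @return list of class \code{"solutionPoint"}: \code{P} (the best
#'   \linkS4class{TransitionMatrix}), \code{coords}, \code{lambdas}
#'   (achieved), \code{score}, \code{converged}, \code{evals}.
#' @export
localSearch <- function(etg, objectives, seed = 1, tol = 1e-6,
                        maxEval = 20000, nStarts = 8, freeRows = NULL) {
  stopifnot(length(objectives) >= 1)
  map <- .coord_map(etg, freeRows)
  if (map$dim == 0) stop("no free parameter: all rows have out-degree 1")
  minim <- checkMinimality(uniformChain(etg))
  if (!minim$irreducible || !minim$aperiodic)
    stop("uniform chain on the graph is not minimal")
  set.seed(seed)
  starts <- list(.coords_of(map, uniformChain(etg)))
  for (k in seq_len(max(0, nStarts - 1))) {
    x <- numeric(map$dim); i <- 1
    for (r in names(map$free)) {
      kk <- length(map$free[[r]])
      w <- stats::rgamma(kk + 1, 1)          # Dirichlet(1) row
      x[i:(i + kk - 1)] <- (w / sum(w))[1:kk]
      i <- i + kk
    }
    starts[[k + 1]] <- x
  }
  evals <- 0
  best <- NULL
  budget_per_start <- ceiling(maxEval / length(starts))
  fn_obj <- function(x) .coord_score(map, x, objectives, etg)
  for (x0 in starts) {
    x <- x0
    f <- fn_obj(x); evals <- evals + 1
    step <- rep(0.25, map$dim)
    used <- 1
    # phase 1: single-row perturbation sweeps with adaptive step
    while (used < budget_per_start / 2 && f > tol && max(step) > 1e-4) {
      improved <- FALSE
      for (j in seq_len(map$dim)) {
        for (sgn in c(1, -1)) {
          xn <- x; xn[j] <- x[j] + sgn * step[j]
          fn <- fn_obj(xn)
          evals <- evals + 1; used <- used + 1
          if (fn < f) { x <- xn; f <- fn; improved <- TRUE; break }
        }
        if (f <= tol || used >= budget_per_start / 2) break
      }
      if (!improved) step <- step / 2
    }
    # phase 2: derivative-free simplex polish of the surviving candidate
    if (f > tol) {
      op <- stats::optim(x, fn_obj, method = "Nelder-Mead",
                         control = list(maxit = max(100, budget_per_start),
                                        reltol = 1e-15,
                                        warn.1d.NelderMead = FALSE))
      evals <- evals + op$counts[["function"]]
      if (op$value < f) { x <- op$par; f <- op$value }
    }
    if (is.null(best) || f < best$f) best <- list(x = x, f = f)
    if (best$f <= tol) break
    if (evals >= maxEval) break
  }
  P <- .tm_from_coords(map, pmax(best$x, 0))
  lam <- .achieved_lambdas(P, objectives, etg)
  structure(list(P = P, coords = best$x, lambdas = lam, score = best$f,
                 converged = best$f <= tol, evals = evals, map = map),
            class = "solutionPoint")
}

#' @export
print.solutionPoint <- function(x, ...) {
  cat(sprintf(
    "Solution point: score %.3g (%sconverged, %d evaluations)\n  achieved lambdas: %s\n",
    x$score, if (x$converged) "" else "NOT ", x$evals,
    paste(signif(x$lambdas, 6), collapse = ", ")))
  invisible(x)
}

#' Source point of an interval-constrained solution set
#'
#' Runs \code{\link{localSearch}} against the midpoints of the objective
#' intervals and checks that the result lies strictly inside every
#' interval.
#'
#' @inheritParams localSearch
#' @return a solution point with an extra \code{interior} flag.
#' @export
sourcePoint <- function(etg, objectives, seed = 1, ...) {
  pt <- localSearch(etg, objectives, seed = seed, ...)
  lam <- pt$lambdas
  lo <- vapply(objectives, `[[`, 0, "lo")
  hi <- vapply(objectives, `[[`, 0, "hi")
  pt$interior <- all(lam > lo & lam < hi) ||
    all(lam >= lo & lam <= hi & lo == hi)  # degenerate intervals
  if (!pt$interior)
    warning("source point does not lie strictly inside all intervals")
  pt
}

.intervals_ok <- function(lam, objectives, tol = 0) {
  lo <- vapply(objectives, `[[`, 0, "lo")
  hi <- vapply(objectives, `[[`, 0, "hi")
  all(lam >= lo - tol & lam <= hi + tol)
}

.point_feasible <- function(map, x, objectives, etg, tol = 0) {
  if (!.coords_feasible(map, x, tol = tol)) return(FALSE)
  P <- tryCatch(.tm_from_coords(map, pmin(pmax(x, 0), 1)),
                error = function(e) NULL)
  if (is.null(P)) return(FALSE)
  lam <- tryCatch(.achieved_lambdas(P, objectives, etg),
                  error = function(e) NULL)
  if (is.null(lam)) return(FALSE)
  .intervals_ok(lam, objectives, tol = tol)
}

#' Boundary point of the solution set along a direction
#'
#' Bisection along the ray from a feasible source point: the step is
#' doubled until infeasibility (an interval endpoint or a simplex face),
#' then bisected until the bracket is tighter than \code{tol}; the last
#' feasible point is returned.
#'
#' @param source a solution point from \code{\link{sourcePoint}} (or
#'   \code{\link{localSearch}}).
#' @param direction numeric vector in free-parameter space (see
#'   \code{source$map$dimnames}).
#' @param objectives interval objectives.
#' @param etg full graph (for phase objectives).
#' @param tol activity tolerance (default 1e-6).
#' @return a solution point on the boundary with \code{t} (ray length) and
#'   \code{active} (description of the near-active constraints).
#' @export
boundaryPoint <- function(source, direction, objectives, etg = NULL,
                          tol = 1e-6) {
  map <- source$map
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-14) stop("direction is numerically zero")
  dir <- direction / nrm
  x0 <- source$coords
  if (!.point_feasible(map, x0, objectives, etg, tol = tol))
    stop("source point is not feasible for the given intervals")
  t_lo <- 0; t_hi <- 0.1
  while (.point_feasible(map, x0 + t_hi * dir, objectives, etg) &&
         t_hi < 1e6) {
    t_lo <- t_hi; t_hi <- 2 * t_hi
  }
  if (t_hi >= 1e6) stop("ray never leaves the solution set")
  for (k in 1:80) {
    if (t_hi - t_lo < tol * 1e-3) break
    mid <- (t_lo + t_hi) / 2
    if (.point_feasible(map, x0 + mid * dir, objectives, etg))
      t_lo <- mid else t_hi <- mid
  }
  x <- pmax(x0 + t_lo * dir, 0)
  P <- .tm_from_coords(map, x)
  lam <- .achieved_lambdas(P, objectives, etg)
  lo <- vapply(objectives, `[[`, 0, "lo")
  hi <- vapply(objectives, `[[`, 0, "hi")
  active <- c(
    if (any(abs(lam - lo) < tol)) "interval lower endpoint",
    if (any(abs(lam - hi) < tol)) "interval upper endpoint",
    if (any(x < tol) || !.coords_feasible(map, x0 + (t_lo + tol) * dir))
      "simplex face")
  structure(list(P = P, coords = x, lambdas = lam,
                 score = sqrt(sum((lam - vapply(objectives, `[[`, 0,
                                                "lambda"))^2)),
                 t = t_lo, active = active, map = map,
                 converged = TRUE),
            class = "solutionPoint")
}

#' Sample the solution set of an interval inference problem
#'
#' Finds the source point, then boundary points along uniformly random
#' unit directions of the free-parameter space.
#'
#' @inheritParams localSearch
#' @param nDirections number of random directions (>= 1).
#' @return a \linkS4class{SolutionSet}.
#' @export
sampleSolutionSet <- function(etg, objectives, nDirections = 20, seed = 1,
                              ...) {
  stopifnot(nDirections >= 1)
  src <- sourcePoint(etg, objectives, seed = seed, ...)
  set.seed(seed + 1)
  D <- src$map$dim
  dirs <- matrix(stats::rnorm(nDirections * D), nDirections, D)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  degenerate <- all(vapply(objectives, function(o) o$lo == o$hi, TRUE))
  bps <- lapply(seq_len(nDirections), function(k) {
    if (degenerate) {
      p <- src; p$t <- 0; p$active <- "degenerate interval"; p
    } else boundaryPoint(src, dirs[k, ], objectives, etg)
  })
  new("SolutionSet", etg = etg, source = unclass(src), boundary = bps,
      directions = dirs, objectives = objectives)
}

setMethod("show", "SolutionSet", function(object) {
  cat(sprintf(
    "SolutionSet: source score %.3g, %d boundary points, dim %d\n",
    object@source$score, length(object@boundary), object@source$map$dim))
})

#' Monte-Carlo volume of a sampled solution set
#'
#' Hit ratio of uniform samples inside the bounding box of the stored
#' points (source plus boundary), feasibility checked by direct eigenvalue
#' evaluation. The volume is expressed in free-parameter coordinates.
#'
#' @param solset a \linkS4class{SolutionSet}.
#' @param mcSamples Monte-Carlo samples.
#' @param seed RNG seed.
#' @return list with \code{volume}, \code{se} (Monte-Carlo standard
#'   error), \code{box} (matrix of bounds), \code{hits}, \code{samples}.
#' @export
estimateVolume <- function(solset, mcSamples = 2000, seed = 1) {
  pts <- rbind(solset@source$coords,
               do.call(rbind, lapply(solset@boundary, `[[`, "coords")))
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  vol_box <- prod(hi - lo)
  if (vol_box <= 0) {
    warning("degenerate bounding box: zero volume")
    return(list(volume = 0, se = 0, box = rbind(lo, hi), hits = 0,
                samples = 0))
  }
  set.seed(seed)
  map <- solset@source$map
  D <- length(lo)
  hits <- 0
  for (k in seq_len(mcSamples)) {
    x <- lo + stats::runif(D) * (hi - lo)
    if (.point_feasible(map, x, solset@objectives, solset@etg)) hits <- hits + 1
  }
  p <- hits / mcSamples
  list(volume = vol_box * p, se = vol_box * sqrt(p * (1 - p) / mcSamples),
       box = rbind(lo, hi), hits = hits, samples = mcSamples)
}

#' Sensitivity ranking of the transitions
#'
#' Each supported probability is multiplied by 1.01 (its row renormalized)
#' and the inference score recomputed; the sensitivity of the transition
#' is the induced score change in percent of the reference score. At an
#' exact optimum (reference score below \code{floor}) the raw score change
#' is ranked instead. Higher sensitivity marks interactions whose precise
#' probability matters most for reproducing the observations.
#'
#' @param point a solution point (from \code{\link{localSearch}}).
#' @param objectives the objective set it was scored against.
#' @param etg full graph (for phase objectives).
#' @param floor reference-score floor (default 1e-9).
#' @return data.frame of class \code{"sensitivityReport"} with columns
#'   \code{from}, \code{to}, \code{probability}, \code{deltaScore},
#'   \code{sensitivity}, sorted in decreasing order.
#' @export
transitionSensitivity <- function(point, objectives, etg = NULL,
                                  floor = 1e-9) {
  P <- point$P
  F_ref <- scoreChain(P, objectives, etg)
  ed <- edgeTable(P)
  ed <- ed[ed$probability > 0, , drop = FALSE]
  delta <- numeric(nrow(ed))
  for (k in seq_len(nrow(ed))) {
    v <- P@values
    v[ed$from[k], ed$to[k]] <- v[ed$from[k], ed$to[k]] * 1.01
    v[ed$from[k], ] <- v[ed$from[k], ] / sum(v[ed$from[k], ])
    Pk <- new("TransitionMatrix", values = v, support = P@support)
    delta[k] <- abs(scoreChain(Pk, objectives, etg) - F_ref)
  }
  sens <- if (F_ref >= floor) 100 * delta / F_ref else delta
  out <- data.frame(from = ed$from, to = ed$to,
                    probability = ed$probability,
                    deltaScore = delta, sensitivity = sens,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$sensitivity, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "referenceScore") <- F_ref
  attr(out, "normalized") <- F_ref >= floor
  class(out) <- c("sensitivityReport", "data.frame")
  out
}

#' Predicted growth-rate distribution of a protein over the solution set
#'
#' Draws interior candidates as convex combinations of the stored source
#' and boundary points (Dirichlet weights), keeps those that still satisfy
#' every interval (the set need not be convex), and evaluates the target
#' protein's Perron growth rate on each.
#'
#' @param solset a \linkS4class{SolutionSet}.
#' @param impact \linkS4class{ImpactMatrix} of the protein to predict (on
#'   the same support).
#' @param nSamples candidate draws.
#' @param seed RNG seed.
#' @return list with \code{lambdas} (feasible draws), \code{mean},
#'   \code{accepted}, \code{attempted}.
#' @export
predictDistribution <- function(solset, impact, nSamples = 200, seed = 1) {
  set.seed(seed)
  map <- solset@source$map
  pts <- rbind(solset@source$coords,
               do.call(rbind, lapply(solset@boundary, `[[`, "coords")))
  m <- nrow(pts)
  lam <- numeric(0)
  for (k in seq_len(nSamples)) {
    w <- stats::rgamma(m, 1); w <- w / sum(w)
    x <- drop(w %*% pts)
    if (!.point_feasible(map, x, solset@objectives, solset@etg)) next
    P <- .tm_from_coords(map, pmax(x, 0))
    lam <- c(lam, dominantEigen(elementaryCost(P, impact))$lambda)
  }
  if (!length(lam)) stop("no feasible sample drawn from the solution set")
  list(lambdas = lam, mean = mean(lam), accepted = length(lam),
       attempted = nSamples)
}
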