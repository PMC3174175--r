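#' @include impact.R
NULL

.as_cost_values <- function(C) {
  if (is(C, "CostMatrix")) C@values else C
}

# fast internal Perron helpers (no support diagnostics): used in inference
# hot loops where the support has been validated once up front
.perron_radius <- function(v) {
  max(Mod(eigen(v, only.values = TRUE)$values))
}

.perron_vectors <- function(v) {
  er <- eigen(v)
  i <- which.max(Mod(er$values))
  right <- Re(er$vectors[, i])
  if (sum(right) < 0) right <- -right
  el <- eigen(t(v))
  j <- which.max(Mod(el$values))
  left <- Re(el$vectors[, j])
  if (sum(left) < 0) left <- -left
  right <- pmax(right, 0); left <- pmax(left, 0)
  right <- right / sum(right)
  left <- left / sum(left * right)
  list(lambda = Re(er$values[i]), left = left, right = right)
}

#' Perron eigenvalue and eigenvectors of a cost matrix
#'
#' For a nonnegative matrix with irreducible, aperiodic support, the
#' dominant eigenvalue is real, positive and simple (Perron-Frobenius);
#' the associated left and right eigenvectors are strictly positive. They
#' are returned normalized so that \code{sum(right) = 1} and
#' \code{left \%*\% right = 1}, the convention used by the asymptotic
#' moment formulas.
#'
#' @param C a \linkS4class{CostMatrix} (or plain nonnegative matrix).
#' @return list with \code{lambda}, \code{left}, \code{right} and
#'   \code{epsilon}, the spectral-gap ratio |second eigenvalue| / lambda
#'   controlling the convergence speed to the permanent regime.
#' @export
dominantEigen <- function(C) {
  v <- .as_cost_values(C)
  if (is(C, "CostMatrix")) {
    s <- C@support
    g <- igraph::graph_from_adjacency_matrix(s * 1, mode = "directed")
    if (igraph::count_components(g, mode = "strong") != 1)
      stop("cost matrix support is reducible: no simple dominant eigenvalue")
    if (.support_period(s) != 1L)
      stop("cost matrix support is periodic: dominant eigenvalue is not simple")
  }
  er <- eigen(v)
  mods <- Mod(er$values)
  i <- which.max(mods)
  lambda <- er$values[i]
  if (abs(Im(lambda)) > 1e-10 * mods[i])
    stop("complex dominant eigenvalue pair: chain is not minimal")
  ties <- sum(mods > (1 - 1e-9) * mods[i])
  if (ties > 1)
    stop("tied dominant eigenvalue moduli: chain is not minimal")
  lambda <- Re(lambda)
  if (lambda <= 0) stop("dominant eigenvalue is not positive")
  right <- Re(er$vectors[, i])
  el <- eigen(t(v))
  j <- which.max(Mod(el$values))
  left <- Re(el$vectors[, j])
  if (sum(right) < 0) right <- -right
  if (sum(left) < 0) left <- -left
  if (any(right < -1e-8 * max(abs(right))) || any(left < -1e-8 * max(abs(left))))
    stop("Perron eigenvectors are not positive: chain is not minimal")
  right <- pmax(right, 0)
  left <- pmax(left, 0)
  right <- right / sum(right)
  left <- left / sum(left * right)
  eps <- if (length(mods) > 1) sort(mods, decreasing = TRUE)[2] / mods[i] else 0
  names(right) <- names(left) <- rownames(v)
  list(lambda = lambda, left = left, right = right, epsilon = eps)
}

#' Growth rate of a protein under a chain
#'
#' Convenience wrapper: Perron eigenvalue of the elementary cost matrix.
#'
#' @param P a \linkS4class{TransitionMatrix}.
#' @param I an \linkS4class{ImpactMatrix}.
#' @export
growthRate <- function(P, I) dominantEigen(elementaryCost(P, I))$lambda

#' Generating matrix of an accumulation rule
#'
#' \code{C(s)} with entries \code{p_ij * i_ij^s}: exponent 0 recovers the
#' transition matrix, exponent 1 the elementary cost matrix, exponent 2 the
#' matrix governing second moments.
#'
#' @param P a \linkS4class{TransitionMatrix}.
#' @param I an \linkS4class{ImpactMatrix} on the same support.
#' @param s real exponent.
#' @return a \linkS4class{CostMatrix}.
#' @export
generatingMatrix <- function(P, I, s) {
  if (any(I@values[I@support] < 0)) stop("negative impact")
  if (!identical(P@support, I@support))
    stop("transition and impact matrices have different supports")
  v <- P@values
  v[P@support] <- v[P@support] * I@values[I@support]^s
  new("CostMatrix", values = v, support = P@support)
}

#' Exact mean of the accumulated cost after n steps
#'
#' The expected product of impacts along a random trajectory of length
#' \code{n} started from \code{v0}: \code{v0' C^n 1}, the cost multiplied
#' along every length-n path, weighted by path probability, summed.
#'
#' @param P a \linkS4class{TransitionMatrix}.
#' @param I an \linkS4class{ImpactMatrix}.
#' @param v0 initial distribution over events (defaults to uniform:
#'   unsynchronized cells).
#' @param n number of steps (>= 0); may be a vector.
#' @return numeric vector of means, one per value of \code{n}.
#' @export
exactMean <- function(P, I, v0 = NULL, n = 1) {
  C <- elementaryCost(P, I)@values
  m <- nrow(C)
  if (is.null(v0)) v0 <- rep(1 / m, m)
  stopifnot(length(v0) == m, abs(sum(v0) - 1) < 1e-9, all(n >= 0))
  nmax <- max(n)
  out <- numeric(length(n))
  vt <- v0
  for (k in 0:nmax) {
    hit <- which(n == k)
    if (length(hit)) out[hit] <- sum(vt)
    if (k < nmax) vt <- drop(vt %*% C)
  }
  out
}

#' Asymptotic (permanent-regime) moments of the accumulated cost
#'
#' In the permanent regime the mean accumulated cost grows as
#' \code{a * lambda1^n} and the second moment as \code{b * lambda2^n},
#' where \code{lambda1}, \code{lambda2} are the Perron eigenvalues of the
#' generating matrices \code{C(1)}, \code{C(2)} and the constants come
#' from their dominant eigenvectors and the initial distribution:
#' \code{a = (v0 . r1)(l1 . 1)} with \code{l1 . r1 = 1}, and analogously
#' for \code{b}. The variance closed form \code{b*lambda2^n -
#' a^2*lambda1^(2n)} is reported when nonnegative; for small \code{n}
#' where cross terms still matter it falls back to the exact second moment
#' via powers of \code{C(2)}.
#'
#' @inheritParams exactMean
#' @param n horizon (vector allowed).
#' @return list with \code{lambda1}, \code{lambda2}, \code{a}, \code{b},
#'   \code{epsilon} (spectral-gap ratio of C(1)), \code{mean} and
#'   \code{variance} vectors along \code{n}.
#' @export
asymptoticStats <- function(P, I, v0 = NULL, n = 1) {
  C1 <- elementaryCost(P, I)
  C2 <- generatingMatrix(P, I, 2)
  m <- nrow(C1@values)
  if (is.null(v0)) v0 <- rep(1 / m, m)
  e1 <- dominantEigen(C1)
  e2 <- dominantEigen(C2)
  a <- sum(v0 * e1$right) * sum(e1$left)
  b <- sum(v0 * e2$right) * sum(e2$left)
  mean_n <- a * e1$lambda^n
  var_n <- b * e2$lambda^n - a^2 * e1$lambda^(2 * n)
  if (any(var_n < 0)) {
    # exact second moment for horizons where the closed form is degenerate
    m2 <- exactMean(P, generatingSquare(I), v0, n[var_n < 0])
    var_n[var_n < 0] <- m2 - exactMean(P, I, v0, n[var_n < 0])^2
  }
  list(lambda1 = e1$lambda, lambda2 = e2$lambda, a = a, b = b,
       epsilon = e1$epsilon, mean = mean_n, variance = var_n)
}

# impact matrix with squared coefficients (helper for exact second moments)
generatingSquare <- function(I) {
  v <- I@values^2
  new("ImpactMatrix", values = v, support = I@support, protein = I@protein,
      s = I@s^2, d = I@d^2, rho = I@rho^2)
}

#' Monte-Carlo simulation of the accumulation rule
#'
#' Draws trajectories of the event chain (initial event from \code{v0},
#' steps from the rows of \code{P} by inverse-CDF sampling, reproducible
#' across platforms) and accumulates the product of impacts.
#'
#' @inheritParams exactMean
#' @param n trajectory length.
#' @param reps number of trajectories.
#' @param seed RNG seed.
#' @return list with \code{costs} (length \code{reps}), \code{mean},
#'   \code{variance}, \code{logNormalKS} (Kolmogorov-Smirnov statistic of
#'   the standardized log-costs against the normal), \code{reps},
#'   \code{seed}.
#' @export
simulateAccumulation <- function(P, I, v0 = NULL, n = 50, reps = 1000,
                                 seed = 1) {
  m <- nrow(P@values)
  if (is.null(v0)) v0 <- rep(1 / m, m)
  stopifnot(reps >= 1, n >= 1)
  set.seed(seed)
  cumP <- t(apply(P@values, 1, cumsum))
  iv <- log(I@values)
  iv[!I@support] <- 0
  state <- findInterval(stats::runif(reps), cumsum(v0),
                        left.open = TRUE) + 1L
  logcost <- numeric(reps)
  for (t in seq_len(n)) {
    u <- stats::runif(reps)
    # inverse-CDF step on each trajectory's current row
    nxt <- rowSums(cumP[state, , drop = FALSE] < u) + 1L
    nxt[nxt > m] <- m
    logcost <- logcost + iv[cbind(state, nxt)]
    state <- nxt
  }
  costs <- exp(logcost)
  lc <- logcost
  z <- (lc - mean(lc)) / stats::sd(lc)
  ks <- if (reps >= 3 && stats::sd(lc) > 0)
    suppressWarnings(stats::ks.test(z, "pnorm")$statistic) else NA_real_
  list(costs = costs, mean = mean(costs),
       variance = stats::var(costs), logNormalKS = unname(ks),
       reps = reps, seed = seed)
}

#' Convergence error of the permanent-regime approximation
#'
#' Relative error, in percent, between the exact finite-horizon mean
#' \code{v0' C^n 1} and its permanent-regime approximation
#' \code{a * lambda1^n}. The error decays like the spectral-gap ratio to
#' the power \code{n}, quantifying how fast the chain enters its permanent
#' regime.
#'
#' @inheritParams exactMean
#' @return numeric vector of percent errors along \code{n}.
#' @export
convergenceError <- function(P, I, v0 = NULL, n = 20) {
  ex <- exactMean(P, I, v0, n)
  st <- asymptoticStats(P, I, v0, n)
  100 * abs(ex - st$mean) / ex
}
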