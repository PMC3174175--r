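#' @include chain.R
NULL

#' Active event sets of a protein
#'
#' Transitions entering \code{protein:+} actively produce the protein;
#' transitions entering \code{protein:-} actively degrade it. Every other
#' transition only lets it decay passively.
#'
#' @param etg an \linkS4class{EventTransitionGraph}.
#' @param protein product identifier.
#' @param allowEmpty if TRUE, missing events give empty sets instead of an
#'   error (useful for auxiliary-only identifiers).
#' @return list with character elements \code{plus} and \code{minus}.
#' @export
activeEventSets <- function(etg, protein, allowEmpty = FALSE) {
  lab <- eventLabels(etg)
  plus <- intersect(.event_label(protein, "+"), lab)
  minus <- intersect(.event_label(protein, "-"), lab)
  if (!allowEmpty && !length(plus) && !length(minus))
    stop(sprintf("product '%s' has no slope event in the graph", protein))
  list(plus = plus, minus = minus)
}

.impact_weights <- function(labels, plus, minus, d, rho) {
  w <- rep(rho, length(labels))
  names(w) <- labels
  w[plus] <- 1 / d
  w[minus] <- d
  w
}

#' Equilibrium calibration of the active degradation coefficient
#'
#' Fixes the active degradation coefficient \code{d} (and production
#' coefficient \code{s = 1/d}) so that, under the uniform chain, the
#' expected protein concentration is asymptotically constant: the Perron
#' eigenvalue of the elementary cost matrix \code{P \%*\% diag(w)} equals
#' one, where the column weight \code{w_j} is \code{s} on the production
#' event, \code{d} on the degradation event and \code{rho} elsewhere.
#'
#' Because the production and degradation events are single columns,
#' \code{d * det(I - P diag(w(d)))} is a degree-two polynomial in \code{d};
#' the calibration is its unique root in (0, 1). The root is verified: the
#' resulting cost matrix must have dominant eigenvalue 1.
#'
#' When \code{rho = 1}, \code{d = 1} is always a root (no passive decay to
#' compensate, stable without active asymmetry); this degenerate case is
#' flagged with a warning and returns \code{d = s = 1}.
#'
#' @param P the uniform \linkS4class{TransitionMatrix} of the graph.
#' @param plus,minus labels of the production / degradation events (each a
#'   single event in this framework).
#' @param rho passive rate, in (0, 1].
#' @return list with \code{d}, \code{s} and \code{lambda} (the verified
#'   dominant eigenvalue, 1 up to solver tolerance).
#' @export
equilibriumDegradation <- function(P, plus, minus, rho) {
  stopifnot(rho > 0, rho <= 1)
  if (length(plus) != 1)
    stop("no production event: equilibrium is undefined (mass_plus = 0)")
  if (length(minus) != 1)
    stop("no degradation event: equilibrium is undefined (mass_minus = 0)")
  lab <- rownames(P@values)
  if (rho == 1) {
    warning("rho = 1: impacts degenerate to all ones (d = s = 1)")
    return(list(d = 1, s = 1, lambda = 1))
  }
  pv <- P@values
  n <- length(lab)
  g <- function(d) {
    w <- .impact_weights(lab, plus, minus, d, rho)
    d * det(diag(n) - pv %*% diag(w))
  }
  # exact interpolation of the degree-two polynomial through three points
  xs <- c(0.25, 0.5, 0.75)
  co <- solve(cbind(1, xs, xs^2), vapply(xs, g, 0))
  disc <- co[2]^2 - 4 * co[1] * co[3]
  if (disc < 0)
    stop(sprintf("equilibrium equation has no real root (discriminant %.4g)", disc))
  roots <- sort(Re(polyroot(co)))
  cand <- roots[roots > 1e-12 & roots < 1 - 1e-12]
  lam_of <- function(d) {
    w <- .impact_weights(lab, plus, minus, d, rho)
    max(Mod(eigen(pv %*% diag(w), only.values = TRUE)$values))
  }
  for (d in cand) {
    lam <- lam_of(d)
    if (abs(lam - 1) < 1e-9)
      return(list(d = d, s = 1 / d, lambda = lam))
  }
  stop(sprintf(
    "no equilibrium root in (0,1) with dominant eigenvalue 1 (roots: %s, discriminant %.4g)",
    paste(signif(roots, 6), collapse = ", "), disc))
}

#' Build the multiplicative impact matrix of a protein
#'
#' Every supported edge entering \code{protein:+} receives the active
#' production coefficient \code{s}; every edge entering \code{protein:-}
#' receives the active degradation coefficient \code{d = 1/s}; every other
#' supported edge receives the passive rate \code{rho}. By default
#' \code{s} and \code{d} come from \code{\link{equilibriumDegradation}} on
#' the uniform chain of the graph, so the uniform elementary cost matrix
#' has Perron eigenvalue exactly one (constant expected concentration in
#' the no-information reference).
#'
#' @param etg an \linkS4class{EventTransitionGraph}.
#' @param protein product identifier.
#' @param rho passive rate (dimensionless multiplicative factor per
#'   non-targeting transition); default 0.95, i.e. a 5\% natural decay.
#' @param condition optional condition label restricting the graph first.
#' @param overrides optional list with explicit \code{s} (and optionally
#'   \code{d}, default \code{1/s}) bypassing the equilibrium solver.
#' @return an \linkS4class{ImpactMatrix}.
#' @export
buildImpactMatrix <- function(etg, protein, rho = 0.95, condition = NULL,
                              overrides = NULL) {
  g <- if (is.null(condition)) etg else applyCondition(etg, condition)
  sets <- activeEventSets(g, protein)
  P <- uniformChain(g)
  minim <- checkMinimality(P)
  if (!minim$irreducible)
    stop("uniform chain on the graph is reducible; impacts are undefined")
  if (!is.null(overrides)) {
    s <- overrides$s
    d <- if (!is.null(overrides$d)) overrides$d else 1 / s
    lam <- NA_real_
  } else {
    eq <- equilibriumDegradation(P, sets$plus, sets$minus, rho)
    s <- eq$s; d <- eq$d
  }
  lab <- rownames(P@values)
  w <- .impact_weights(lab, sets$plus, sets$minus, d, rho)
  v <- matrix(rep(w, each = length(lab)), length(lab), length(lab),
              dimnames = dimnames(P@values))
  v[!P@support] <- 0
  new("ImpactMatrix", values = v, support = P@support, protein = protein,
      s = s, d = d, rho = rho)
}

#' @describeIn buildImpactMatrix accessor for the impact values.
#' @param x an ImpactMatrix.
#' @export
setMethod("values", "ImpactMatrix", function(x) x@values)

#' @describeIn buildImpactMatrix accessor for the support.
#' @export
setMethod("support", "ImpactMatrix", function(x) x@support)

#' @describeIn buildImpactMatrix event labels.
#' @export
setMethod("eventLabels", "ImpactMatrix", function(x) rownames(x@values))

setMethod("show", "ImpactMatrix", function(object) {
  cat(sprintf(
    "ImpactMatrix for '%s': s = %.6g, d = %.6g, rho = %.6g (%d edges)\n",
    object@protein, object@s, object@d, object@rho, sum(object@support)))
})

#' Elementary cost matrix
#'
#' Entrywise product \code{c_ij = p_ij * i_ij} of transition probabilities
#' and impacts. Its Perron eigenvalue is the per-transition growth factor
#' of the expected accumulated protein concentration.
#'
#' @param P a \linkS4class{TransitionMatrix}.
#' @param I an \linkS4class{ImpactMatrix} on the same support.
#' @return a \linkS4class{CostMatrix}.
#' @export
elementaryCost <- function(P, I) {
  if (!identical(dim(P@values), dim(I@values)) ||
      !identical(rownames(P@values), rownames(I@values)))
    stop("transition and impact matrices are indexed differently")
  if (!identical(P@support, I@support))
    stop("transition and impact matrices have different supports")
  new("CostMatrix", values = P@values * I@values, support = P@support)
}

#' @describeIn elementaryCost accessor for the cost values.
#' @param x a CostMatrix.
#' @export
setMethod("values", "CostMatrix", function(x) x@values)

#' @describeIn elementaryCost accessor for the support.
#' @export
setMethod("support", "CostMatrix", function(x) x@support)

#' @describeIn elementaryCost event labels.
#' @export
setMethod("eventLabels", "CostMatrix", function(x) rownames(x@values))

setMethod("show", "CostMatrix", function(object) {
  cat(sprintf("CostMatrix: %d events, %d supported edges\n",
              nrow(object@values), sum(object@support)))
  print(round(object@values, 4))
})
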