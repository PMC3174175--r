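#' @import methods
NULL

.SIGN_LEVELS <- c("+", "-")

#' EventTransitionGraph: the qualitative skeleton of an event chain
#'
#' Nodes are *events*: a constant slope direction (\code{+} increase,
#' \code{-} decrease) of one gene product over a time unit, or an auxiliary
#' compound event (a signed pair is not required for auxiliaries, e.g. a
#' complex formation). Directed edges encode which event can immediately
#' succeed which. Each edge may carry an environmental condition label; an
#' edge with condition \code{NA} exists under every condition.
#'
#' Event labels are written \code{product:sign} (e.g. \code{fis:+});
#' auxiliary events use their bare name. Events are canonically ordered by
#' product name then sign, auxiliaries last, so that derived matrices are
#' reproducible across runs.
#'
#' @slot events data.frame with columns \code{product}, \code{sign}
#'   (\code{+}, \code{-} or \code{NA} for auxiliaries), \code{kind}
#'   (\code{"transcriptional"} or \code{"auxiliary"}) and \code{label}.
#' @slot edges data.frame with integer columns \code{from}, \code{to}
#'   (1-based indices into \code{events}) and character column
#'   \code{condition} (\code{NA} = unconditional).
#' @slot conditions declared condition labels; a declared condition that
#'   tags no edge is legitimate (it selects the unconditional subgraph).
#' @export
setClass("EventTransitionGraph",
  representation(events = "data.frame", edges = "data.frame",
                 conditions = "character"))

setValidity("EventTransitionGraph", function(object) {
  ev <- object@events
  ed <- object@edges
  msgs <- character()
  need <- c("product", "sign", "kind", "label")
  if (!all(need %in% names(ev)))
    return(sprintf("events must have columns %s", paste(need, collapse = ", ")))
  if (!all(c("from", "to", "condition") %in% names(ed)))
    return("edges must have columns from, to, condition")
  if (any(!nzchar(ev$product)))
    msgs <- c(msgs, "event products must be nonempty")
  ok_sign <- is.na(ev$sign) | ev$sign %in% .SIGN_LEVELS
  if (!all(ok_sign))
    msgs <- c(msgs, "event signs must be '+', '-' or NA (auxiliary)")
  if (anyDuplicated(ev$label))
    msgs <- c(msgs, "duplicate event labels")
  if (nrow(ed) > 0) {
    if (any(ed$from < 1 | ed$from > nrow(ev) | ed$to < 1 | ed$to > nrow(ev)))
      msgs <- c(msgs, "edge endpoint index out of range")
    key <- paste(ed$from, ed$to, ifelse(is.na(ed$condition), "", ed$condition))
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate edges")
  }
  if (length(msgs)) msgs else TRUE
})

#' TransitionMatrix: row-stochastic probabilities on an ETG support
#'
#' A square nonnegative matrix indexed by event labels. Rows sum to one
#' (tolerance 1e-9) and entries outside the supporting edge set are exactly
#' zero. The support is stored explicitly so that zero probabilities on
#' existing edges are distinguishable from absent edges.
#'
#' @slot values numeric matrix with identical row/column dimnames.
#' @slot support logical matrix, TRUE on ETG edges.
#' @export
setClass("TransitionMatrix",
  representation(values = "matrix", support = "matrix"))

setValidity("TransitionMatrix", function(object) {
  v <- object@values
  s <- object@support
  msgs <- character()
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (!identical(dim(v), dim(s))) return("values and support differ in shape")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msgs <- c(msgs, "row and column names must be identical event labels")
  if (any(v < 0)) msgs <- c(msgs, "negative probabilities")
  if (any(v[!s] != 0)) msgs <- c(msgs, "nonzero entry outside support")
  rs <- rowSums(v)
  if (any(abs(rs - 1) > 1e-9))
    msgs <- c(msgs, sprintf("row sums deviate from 1 (max |1-sum| = %.3g)",
                            max(abs(rs - 1))))
  if (length(msgs)) msgs else TRUE
})

#' ImpactMatrix: per-protein multiplicative transition effects
#'
#' Each supported transition multiplies the protein concentration by one of
#' three coefficients: the active production coefficient \code{s} on edges
#' entering the protein's \code{+} event, the active degradation
#' coefficient \code{d = 1/s} on edges entering its \code{-} event, and the
#' passive rate \code{rho} elsewhere (natural degradation).
#'
#' @slot values numeric matrix (positive on the support, zero elsewhere).
#' @slot support logical matrix.
#' @slot protein product identifier.
#' @slot s,d,rho the three coefficient values used.
#' @export
setClass("ImpactMatrix",
  representation(values = "matrix", support = "matrix", protein = "character",
                 s = "numeric", d = "numeric", rho = "numeric"))

setValidity("ImpactMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (any(v[object@support] <= 0)) msgs <- c(msgs, "nonpositive impact on support")
  if (any(v[!object@support] != 0)) msgs <- c(msgs, "nonzero impact outside support")
  if (length(object@s) == 1 && length(object@d) == 1 &&
      abs(object@s * object@d - 1) > 1e-12)
    msgs <- c(msgs, "s * d must equal 1")
  if (length(msgs)) msgs else TRUE
})

#' CostMatrix: entrywise product of probabilities and impacts
#'
#' The elementary cost matrix \code{C} with \code{c_ij = p_ij * i_ij}. Its
#' Perron eigenvalue is the per-transition growth factor of the expected
#' accumulated concentration.
#'
#' @slot values nonnegative numeric matrix.
#' @slot support logical matrix (shared with the transition matrix).
#' @export
setClass("CostMatrix",
  representation(values = "matrix", support = "matrix"))

setValidity("CostMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (any(v < 0)) return("negative cost")
  if (any(v[!object@support] != 0)) return("nonzero cost outside support")
  TRUE
})

#' SolutionSet: sampled polytope of transition matrices
#'
#' Approximation of the set of transition matrices whose growth rates fall
#' inside objective intervals: a central source point plus boundary points
#' reached by bisection along random directions in the free-parameter
#' space (one coordinate per supported edge minus one per row, see
#' \code{\link{freeCoordinates}}).
#'
#' @slot etg the underlying \linkS4class{EventTransitionGraph}.
#' @slot source a solution point (list with elements \code{P},
#'   \code{coords}, \code{lambdas}, \code{score}, \code{converged}).
#' @slot boundary list of solution points on the boundary.
#' @slot directions matrix of the unit directions used (rows).
#' @slot objectives the interval objective set used.
#' @export
setClass("SolutionSet",
  representation(etg = "EventTransitionGraph", source = "list",
                 boundary = "list", directions = "matrix",
                 objectives = "list"))
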