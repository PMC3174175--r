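#' @include AllClasses.R
NULL

#' Event labels of an object
#'
#' @param x an object carrying an event index.
#' @return character vector of event labels in canonical order.
#' @export
setGeneric("eventLabels", function(x) standardGeneric("eventLabels"))

#' Number of events
#' @param x an object carrying an event index.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' Edge table of a graph-like object
#'
#' @param x an object with a supporting edge set.
#' @return data.frame with columns \code{from}, \code{to} (event labels) and
#'   \code{condition} where applicable.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Numeric matrix stored in a matrix-like S4 object
#' @param x a TransitionMatrix, ImpactMatrix or CostMatrix.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Support (allowed edges) of a matrix-like S4 object
#' @param x a TransitionMatrix, ImpactMatrix or CostMatrix.
#' @return logical matrix.
#' @export
setGeneric("support", function(x) standardGeneric("support"))

#' Restrict a graph to one environmental condition
#'
#' Keeps the edges that are unconditional or tagged with \code{condition}.
#'
#' @param x an \linkS4class{EventTransitionGraph}.
#' @param condition condition label (character scalar).
#' @export
setGeneric("applyCondition", function(x, condition) standardGeneric("applyCondition"))
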