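#' @include AllGenerics.R
NULL

.event_label <- function(product, sign) {
  ifelse(is.na(sign), product, paste0(product, ":", sign))
}

.parse_event_label <- function(label) {
  has_sign <- grepl(":[+-]$", label)
  product <- ifelse(has_sign, sub(":[+-]$", "", label), label)
  sign <- ifelse(has_sign, substr(label, nchar(label), nchar(label)), NA_character_)
  data.frame(product = product, sign = sign,
             kind = ifelse(has_sign, "transcriptional", "auxiliary"),
             label = label, stringsAsFactors = FALSE)
}

# canonical event order: product name, then sign (+ before -), auxiliaries last
.canonical_event_order <- function(events) {
  aux <- events$kind == "auxiliary"
  order(aux, events$product, match(events$sign, .SIGN_LEVELS), method = "radix")
}

#' Build an event transition graph from labeled edges
#'
#' @param from,to character vectors of event labels (\code{product:sign},
#'   bare names for auxiliary events such as \code{"complex"}).
#' @param condition optional character vector of condition labels per edge;
#'   \code{NA} (default) means the edge exists under every condition.
#' @param conditions optional declared condition labels beyond those on the
#'   edges (a condition under which every conditional edge is absent).
#' @return an \linkS4class{EventTransitionGraph} with events in canonical
#'   order (sorted by product then sign, auxiliaries last) and duplicate
#'   edges collapsed.
#' @examples
#' etg <- EventTransitionGraph(from = c("x:+", "x:-"), to = c("x:-", "x:+"))
#' eventLabels(etg)
#' @export
EventTransitionGraph <- function(from, to, condition = NA_character_,
                                 conditions = character()) {
  stopifnot(length(from) == length(to))
  condition <- rep_len(as.character(condition), length(from))
  labels <- unique(c(from, to))
  events <- .parse_event_label(labels)
  events <- events[.canonical_event_order(events), , drop = FALSE]
  rownames(events) <- NULL
  idx <- function(l) match(l, events$label)
  edges <- data.frame(from = idx(from), to = idx(to),
                      condition = condition, stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges), , drop = FALSE]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  conditions <- unique(c(conditions, condition[!is.na(condition)]))
  new("EventTransitionGraph", events = events, edges = edges,
      conditions = conditions)
}

#' @describeIn EventTransitionGraph event labels in canonical order.
#' @param x an EventTransitionGraph.
#' @export
setMethod("eventLabels", "EventTransitionGraph", function(x) x@events$label)

#' @describeIn EventTransitionGraph number of events.
#' @export
setMethod("nEvents", "EventTransitionGraph", function(x) nrow(x@events))

#' @describeIn EventTransitionGraph edge list with event labels.
#' @export
setMethod("edgeTable", "EventTransitionGraph", function(x) {
  data.frame(from = x@events$label[x@edges$from],
             to = x@events$label[x@edges$to],
             condition = x@edges$condition, stringsAsFactors = FALSE)
})

#' Events table of a graph
#'
#' @param etg an \linkS4class{EventTransitionGraph}.
#' @return data.frame with columns product, sign, kind, label.
#' @export
eventTable <- function(etg) etg@events

#' Condition labels present on a graph's edges
#' @param etg an \linkS4class{EventTransitionGraph}.
#' @export
conditionLabels <- function(etg) {
  unique(c(etg@conditions, etg@edges$condition[!is.na(etg@edges$condition)]))
}

setMethod("show", "EventTransitionGraph", function(object) {
  nc <- length(conditionLabels(object))
  cat(sprintf("EventTransitionGraph: %d events, %d edges%s\n",
              nEvents(object), nrow(object@edges),
              if (nc) sprintf(" (%d condition label%s)", nc, if (nc > 1) "s" else "")
              else ""))
  cat("  events:", paste(eventLabels(object), collapse = " "), "\n")
})

#' @describeIn applyCondition keep edges unconditional or tagged with
#'   \code{condition}; errors on an unknown label (unless the graph has no
#'   conditional edges at all, in which case any condition is a no-op).
#' @export
setMethod("applyCondition", "EventTransitionGraph", function(x, condition) {
  stopifnot(is.character(condition), length(condition) == 1)
  known <- conditionLabels(x)
  if (length(known) && !condition %in% known)
    stop(sprintf("unknown condition label '%s' (known: %s)", condition,
                 paste(known, collapse = ", ")))
  keep <- is.na(x@edges$condition) | x@edges$condition == condition
  new("EventTransitionGraph", events = x@events,
      edges = x@edges[keep, , drop = FALSE], conditions = x@conditions)
})

#' Derive an event transition graph from a qualitative state graph
#'
#' Under the asynchronous convention every state transition changes exactly
#' one variable, defining an event (the changed variable and its
#' direction). For every length-2 path \code{s1 -> s2 -> s3} of the state
#' graph, the ETG receives an edge from the event of \code{s1 -> s2} to the
#' event of \code{s2 -> s3}; duplicates collapse. Returned events are
#' exactly those appearing on some transition. Self-successions
#' (\code{x:+ -> x:+}) are kept when the state graph produces them.
#'
#' @param stg data.frame describing state transitions with columns
#'   \code{from}, \code{to} (state identifiers), \code{changed_var} and
#'   \code{direction} (\code{+}/\code{-}). An optional \code{levels} column
#'   (comma-separated discrete levels per state, aligned with \code{from})
#'   enables checking the single-change convention.
#' @return an \linkS4class{EventTransitionGraph}.
#' @examples
#' stg <- data.frame(from = c("a", "b"), to = c("b", "a"),
#'                   changed_var = "x", direction = c("+", "-"))
#' edgeTable(etgFromStateGraph(stg))
#' @export
etgFromStateGraph <- function(stg) {
  need <- c("from", "to", "changed_var", "direction")
  if (!all(need %in% names(stg)))
    stop("state graph needs columns from, to, changed_var, direction")
  if (!all(stg$direction %in% .SIGN_LEVELS))
    stop("malformed state graph: direction must be '+' or '-'")
  if (!is.null(stg$levels)) {
    lvl <- strsplit(as.character(stg$levels), ",")
    lvl <- lapply(lvl, as.numeric)
    names(lvl) <- as.character(stg$from)
    for (i in seq_len(nrow(stg))) {
      la <- lvl[[as.character(stg$from[i])]]
      lb <- lvl[[as.character(stg$to[i])]]
      if (is.null(lb)) next  # terminal states never appear as 'from'
      if (length(la) != length(lb))
        stop("malformed state graph: level vectors differ in length")
      if (sum(la != lb) != 1)
        stop("malformed state graph: each transition must change exactly one variable")
    }
  }
  ev <- .event_label(stg$changed_var, stg$direction)
  # length-2 paths: transition t1 ending where transition t2 starts
  from <- character(0); to <- character(0)
  for (i in seq_len(nrow(stg))) {
    succ <- which(stg$from == stg$to[i])
    if (length(succ)) {
      from <- c(from, rep(ev[i], length(succ)))
      to <- c(to, ev[succ])
    }
  }
  if (!length(from))
    stop("state graph has no length-2 path; no event succession can be derived")
  EventTransitionGraph(from = from, to = to)
}
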