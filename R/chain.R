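#' @include etg.R
NULL

.support_matrix <- function(etg, condition = NULL) {
  g <- if (is.null(condition)) etg else applyCondition(etg, condition)
  n <- nEvents(g)
  s <- matrix(FALSE, n, n, dimnames = list(eventLabels(g), eventLabels(g)))
  ed <- unique(g@edges[c("from", "to")])
  s[cbind(ed$from, ed$to)] <- TRUE
  s
}

.new_transition_matrix <- function(values, support) {
  new("TransitionMatrix", values = values, support = support)
}

#' @describeIn TransitionMatrix the probability matrix itself.
#' @param x a TransitionMatrix.
#' @export
setMethod("values", "TransitionMatrix", function(x) x@values)

#' @describeIn TransitionMatrix logical support matrix.
#' @export
setMethod("support", "TransitionMatrix", function(x) x@support)

#' @describeIn TransitionMatrix event labels indexing the matrix.
#' @export
setMethod("eventLabels", "TransitionMatrix", function(x) rownames(x@values))

#' @describeIn TransitionMatrix number of events.
#' @export
setMethod("nEvents", "TransitionMatrix", function(x) nrow(x@values))

#' @describeIn TransitionMatrix supported edges with their probabilities.
#' @export
setMethod("edgeTable", "TransitionMatrix", function(x) {
  idx <- which(x@support, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(from = rownames(x@values)[idx[, 1]],
             to = colnames(x@values)[idx[, 2]],
             probability = x@values[idx], stringsAsFactors = FALSE)
})

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix: %d events, %d supported edges\n",
              nEvents(object), sum(object@support)))
  print(round(object@values, 4))
})

#' Construct a transition matrix from explicit probabilities
#'
#' @param values square numeric matrix with event labels as dimnames.
#' @param support optional logical support matrix; defaults to the nonzero
#'   pattern of \code{values}.
#' @export
TransitionMatrix <- function(values, support = values != 0) {
  .new_transition_matrix(values, support)
}

#' Uniform chain on an event transition graph
#'
#' Distributes each event's outgoing probability mass equally over its
#' out-edges. This is the no-information reference chain used by the
#' equilibrium calibration of impact coefficients.
#'
#' @param etg an \linkS4class{EventTransitionGraph}.
#' @param condition optional condition label to restrict the edge set first.
#' @return a \linkS4class{TransitionMatrix}.
#' @export
uniformChain <- function(etg, condition = NULL) {
  s <- .support_matrix(etg, condition)
  outdeg <- rowSums(s)
  if (any(outdeg == 0))
    stop(sprintf("dead-end event(s) with no outgoing edge: %s",
                 paste(rownames(s)[outdeg == 0], collapse = ", ")))
  v <- s / outdeg
  .new_transition_matrix(v, s)
}

#' Stationary distribution of an irreducible chain
#'
#' Solves \code{pi P = pi} with \code{pi >= 0}, \code{sum(pi) = 1} via the
#' left eigenvector of the unit eigenvalue.
#'
#' @param P a \linkS4class{TransitionMatrix}, irreducible.
#' @return named probability vector over events.
#' @export
stationaryDistribution <- function(P) {
  rep_ <- checkMinimality(P)
  if (!rep_$irreducible)
    stop("chain is reducible: stationary distribution is not unique")
  e <- eigen(t(P@values))
  i <- which.min(abs(e$values - 1))
  pi <- Re(e$vectors[, i])
  pi <- pi / sum(pi)
  if (any(pi < -1e-10))
    stop("failed to extract a nonnegative stationary vector")
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  err <- max(abs(drop(pi %*% P@values) - pi))
  if (err > 1e-10)
    stop(sprintf("stationary solve did not converge (residual %.3g)", err))
  names(pi) <- rownames(P@values)
  pi
}

# gcd of cycle lengths on a strongly connected support via BFS level trick
.support_period <- function(s) {
  n <- nrow(s)
  level <- rep(NA_integer_, n)
  level[1] <- 0L
  queue <- 1L
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in which(s[u, ])) {
      if (is.na(level[v])) {
        level[v] <- level[u] + 1L
        queue <- c(queue, v)
      }
    }
  }
  g <- 0L
  idx <- which(s, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    d <- level[idx[k, 1]] + 1L - level[idx[k, 2]]
    g <- if (g == 0L) abs(d) else {
      a <- g; b <- abs(d)
      while (b != 0L) { t <- b; b <- a %% b; a <- t }
      a
    }
  }
  if (g == 0L) 1L else g
}

#' Minimality (irreducibility and aperiodicity) of a chain
#'
#' A chain is minimal when its support graph is strongly connected
#' (irreducible) and the gcd of its cycle lengths is one (aperiodic).
#' Minimality is required by the asymptotic accumulation theory: only then
#' is the Perron eigenvalue of a cost matrix simple and dominant.
#'
#' @param P a \linkS4class{TransitionMatrix} (or an
#'   \linkS4class{EventTransitionGraph}, in which case the support is
#'   taken from its edges).
#' @return list with elements \code{irreducible}, \code{aperiodic} and
#'   \code{period} (1 when aperiodic; \code{NA} when reducible).
#' @export
checkMinimality <- function(P) {
  s <- if (is(P, "EventTransitionGraph")) .support_matrix(P) else P@support
  g <- igraph::graph_from_adjacency_matrix(s * 1, mode = "directed")
  irr <- igraph::count_components(g, mode = "strong") == 1
  if (!irr)
    return(list(irreducible = FALSE, aperiodic = FALSE, period = NA_integer_))
  p <- .support_period(s)
  list(irreducible = TRUE, aperiodic = p == 1L, period = p)
}

#' Restrict a transition matrix to a new edge set and renormalize
#'
#' Reuses an inferred matrix after a condition switch: probabilities on
#' removed edges are dropped and each affected row is renormalized to sum
#' one. Edges present in the new graph but absent from the old support
#' receive an equal split of \code{reserve} mass per row (default 0: new
#' edges get probability zero, unless a row would otherwise have no mass,
#' in which case its mass is split equally over all its out-edges).
#'
#' @param P a \linkS4class{TransitionMatrix}.
#' @param etg2 the target \linkS4class{EventTransitionGraph} (or a
#'   condition-filtered version of the original graph).
#' @param condition optional condition label applied to \code{etg2} first.
#' @param reserve probability mass granted to newly added edges per row.
#' @return a \linkS4class{TransitionMatrix} on the new support.
#' @export
restrictRenormalize <- function(P, etg2, condition = NULL, reserve = 0) {
  stopifnot(reserve >= 0, reserve < 1)
  s2 <- .support_matrix(etg2, condition)
  lab <- rownames(P@values)
  if (!setequal(lab, rownames(s2)))
    stop("event sets differ between matrix and target graph")
  s2 <- s2[lab, lab]
  v <- P@values * s2
  newed <- s2 & !P@support
  for (i in seq_along(lab)) {
    out <- which(s2[i, ])
    if (!length(out))
      stop(sprintf("dead-end event after restriction: %s", lab[i]))
    kept <- sum(v[i, ])
    nn <- sum(newed[i, ])
    if (kept <= 0) {
      v[i, out] <- 1 / length(out)
    } else if (nn > 0 && reserve > 0) {
      v[i, ] <- v[i, ] * (1 - reserve) / kept
      v[i, newed[i, ]] <- reserve / nn
    } else {
      v[i, ] <- v[i, ] / kept
    }
  }
  .new_transition_matrix(v, s2)
}
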