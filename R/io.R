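#' @include fixtures.R
NULL

#' Read / write event transition graphs as TSV
#'
#' The exchange format is a tab-separated file with header
#' \code{source<TAB>target<TAB>condition}; events written as
#' \code{product:sign} (bare names for auxiliary events), empty condition
#' meaning unconditional. Lines starting with \code{#} are comments.
#'
#' @param file path.
#' @return \code{readEtg}: an \linkS4class{EventTransitionGraph}.
#' @export
readEtg <- function(file) {
  d <- utils::read.table(file, sep = "\t", header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE, quote = "",
                         colClasses = "character")
  if (!all(c("source", "target") %in% names(d)))
    stop("ETG file needs 'source' and 'target' columns")
  cond <- if ("condition" %in% names(d)) d$condition else NA_character_
  cond[!is.na(cond) & cond == ""] <- NA_character_
  EventTransitionGraph(from = d$source, to = d$target, condition = cond)
}

#' @rdname readEtg
#' @param etg graph to write.
#' @export
writeEtg <- function(etg, file) {
  ed <- edgeTable(etg)
  ed$condition[is.na(ed$condition)] <- ""
  names(ed) <- c("source", "target", "condition")
  utils::write.table(ed, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a state transition graph from TSV
#'
#' Format: \code{state_id<TAB>levels<TAB>successor_id<TAB>changed_var<TAB>
#' direction} with comma-separated discrete levels.
#'
#' @param file path.
#' @return data.frame suitable for \code{\link{etgFromStateGraph}}.
#' @export
readStateGraph <- function(file) {
  d <- utils::read.table(file, sep = "\t", header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE, quote = "",
                         colClasses = "character")
  need <- c("state_id", "levels", "successor_id", "changed_var", "direction")
  if (!all(need %in% names(d)))
    stop(sprintf("state graph file needs columns %s",
                 paste(need, collapse = ", ")))
  data.frame(from = d$state_id, to = d$successor_id, levels = d$levels,
             changed_var = d$changed_var, direction = d$direction,
             stringsAsFactors = FALSE)
}

#' Read / write event-indexed matrices as dense CSV
#'
#' Dense CSV with event labels as header row and first column.
#'
#' @param file path.
#' @param what one of \code{"transition"}, \code{"cost"} — the class to
#'   wrap the values in (\code{"plain"} returns the bare matrix).
#' @export
readEventMatrix <- function(file, what = c("transition", "cost", "plain")) {
  what <- match.arg(what)
  d <- utils::read.csv(file, check.names = FALSE, row.names = 1)
  m <- as.matrix(d)
  colnames(m) <- colnames(d)
  if (!identical(rownames(m), colnames(m)))
    stop("matrix CSV must have identical row and column event labels")
  switch(what,
         transition = TransitionMatrix(m),
         cost = new("CostMatrix", values = m, support = m != 0),
         plain = m)
}

#' @rdname readEventMatrix
#' @param x a TransitionMatrix, ImpactMatrix, CostMatrix or plain matrix.
#' @export
writeEventMatrix <- function(x, file) {
  m <- if (is.matrix(x)) x else values(x)
  utils::write.csv(as.data.frame(m), file, row.names = TRUE)
  invisible(file)
}

#' Read a protein concentration series from CSV
#'
#' Header \code{time_min,concentration}, one file per protein.
#'
#' @param file path.
#' @param protein identifier (defaults to the file base name).
#' @export
readProteinSeries <- function(file, protein = NULL) {
  d <- utils::read.csv(file)
  if (!all(c("time_min", "concentration") %in% names(d)))
    stop("series CSV needs columns time_min, concentration")
  if (is.null(protein))
    protein <- sub("\\.[^.]*$", "", basename(file))
  proteinSeries(d$time_min, d$concentration, protein)
}

#' @rdname readProteinSeries
#' @param series a \code{\link{proteinSeries}}.
#' @export
writeProteinSeries <- function(series, file) {
  utils::write.csv(series[c("time_min", "concentration")], file,
                   row.names = FALSE)
  invisible(file)
}

#' Read growth objectives from CSV
#'
#' Format: \code{protein,phase,lambda_lo,lambda_hi} (\code{lo = hi} for
#' exact objectives; empty phase = unconditional).
#'
#' @param file path.
#' @return data.frame.
#' @export
readObjectivesTable <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("protein", "phase", "lambda_lo", "lambda_hi")
  if (!all(need %in% names(d)))
    stop(sprintf("objectives CSV needs columns %s",
                 paste(need, collapse = ", ")))
  d$phase[is.na(d$phase) | d$phase == ""] <- NA_character_
  d
}

#' Read a case-study configuration from YAML
#'
#' Expected top-level fields: \code{fixture} (\code{"two-gene"} or
#' \code{"carbon-starvation"}) or \code{etg_file}; \code{proteins} (list
#' of \code{name}, \code{passive_rate}, \code{half_life_min}); optional
#' \code{condition}, \code{objectives} (list of \code{protein},
#' \code{lambda} or \code{lo}/\code{hi}), \code{horizon_min},
#' \code{delta_min}, \code{cutpoints}.
#'
#' @param file path to a YAML file.
#' @export
readConfig <- function(file) yaml::read_yaml(file)
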