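#' Packaged dataset-count fixtures
#'
#' The package ships the 25-trial dataset-size grids of the data-collection
#' protocol it emulates: `"table1"` holds per-trial sample counts for the
#' ten road-condition motion states (25 x 10), `"table2"` per-trial sample
#' counts for the six level-walking gait phases plus the LW total column
#' (25 x 7). All cells are positive integers and every column sum equals
#' the grid's total row.
#'
#' @param table_id `"table1"` (road conditions) or `"table2"` (gait phases).
#' @return A `count_fixture`: data frame with a `trial` column and integer
#'   count columns.
#' @export
#' @examples
#' fx <- load_count_fixture("table2")
#' fx$LW[1]
load_count_fixture <- function(table_id = c("table1", "table2")) {
  table_id <- match.arg(table_id)
  file <- switch(table_id,
                 table1 = "counts_road_conditions.csv",
                 table2 = "counts_gait_phase.csv")
  path <- system.file("extdata", file, package = "gaitrec", mustWork = TRUE)
  fx <- utils::read.csv(path, check.names = FALSE)
  stopifnot(nrow(fx) == 25, all(fx[-1] > 0))
  attr(fx, "table_id") <- table_id
  class(fx) <- c("count_fixture", "data.frame")
  fx
}

#' Packaged reference confusion matrices
#'
#' Column-normalized confusion matrices reported for the full-scale state
#' and phase recognizers (rows = predicted class, columns = true class;
#' each column sums to 1 within printed rounding). Useful as a qualitative
#' reference for the near-diagonal structure the synthetic benchmarks stand
#' in for.
#'
#' @param kind `"state"` (10 motion states) or `"phase"` (6 gait phases).
#' @return Numeric matrix with class names on both dimensions.
#' @export
load_reference_confusion <- function(kind = c("state", "phase")) {
  kind <- match.arg(kind)
  file <- paste0("reference_confusion_", kind, ".csv")
  path <- system.file("extdata", file, package = "gaitrec", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
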