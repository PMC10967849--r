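#' Read and write IMU streams and event timelines as CSV
#'
#' An IMU stream CSV has a header `time_s,<sensor>_<gx|gy|gz|ax|ay|az>` for
#' the five sensors in canonical order and one row per sample, time strictly
#' increasing at the sampling interval. An event timeline CSV has columns
#' `sample_index,side,event` with side in {L, R} and event in
#' {HS, TO, HMax}.
#'
#' @param stream An `imu_stream` data frame.
#' @param path File path.
#' @return Readers return the object; writers return `path` invisibly.
#' @name gait_io
NULL

#' @rdname gait_io
#' @export
write_imu_stream <- function(stream, path) {
  stopifnot(identical(names(stream), c("time_s", gait_channels())))
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE)
  invisible(path)
}

#' @rdname gait_io
#' @param sample_rate Sampling rate attached to the stream; inferred from
#'   the time column when `NULL`.
#' @export
read_imu_stream <- function(path, sample_rate = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(c("time_s", gait_channels()), names(df))
  if (length(missing))
    stop("stream is missing channel(s): ", paste(missing, collapse = ", "))
  df <- df[, c("time_s", gait_channels())]
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing")
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(dt)
  class(df) <- c("imu_stream", "data.frame")
  attr(df, "sample_rate") <- sample_rate
  df
}

#' @rdname gait_io
#' @param timeline An `event_timeline` data frame.
#' @export
write_event_timeline <- function(timeline, path) {
  stopifnot(all(c("sample_index", "side", "event") %in% names(timeline)))
  utils::write.csv(as.data.frame(timeline)[, c("sample_index", "side", "event")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname gait_io
#' @export
read_event_timeline <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("sample_index", "side", "event") %in% names(df)))
  if (!all(df$side %in% event_sides())) stop("side must be L or R")
  if (!all(df$event %in% event_kinds())) stop("event must be HS, TO or HMax")
  df$sample_index <- as.integer(df$sample_index)
  class(df) <- c("event_timeline", "data.frame")
  df
}
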