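#' Fit per-channel standardization statistics on training streams
#'
#' Computes the mean and population (divisor-n) standard deviation of each
#' of the 30 channels over all samples of the training streams. The statistics are a pure function
#' of the training data; test streams are standardized with them unchanged,
#' so no information leaks from test to train. Channels with zero variance
#' are flagged constant and standardized with a unit divisor.
#'
#' @param streams A list of `imu_stream` data frames (or a single stream).
#' @return A `channel_stats` object: list with `mean`, `sd` and `constant`
#'   (logical), each named by channel.
#' @export
fit_stats <- function(streams) {
  if (inherits(streams, "imu_stream")) streams <- list(streams)
  if (!length(streams)) stop("cannot fit statistics on an empty training set")
  ch <- gait_channels()
  X <- do.call(rbind, lapply(streams, function(s) as.matrix(s[, ch])))
  mu <- colMeans(X)
  # population standard deviation (divisor n), the usual scaler convention
  sd_ <- sqrt(colMeans(sweep(X, 2, mu)^2))
  constant <- sd_ <= 0 | !is.finite(sd_)
  sd_[constant] <- 1
  structure(list(mean = mu, sd = sd_, constant = constant),
            class = "channel_stats")
}

#' Standardize a stream with fitted channel statistics
#'
#' Applies `(x - mean) / sd` per channel. Inverse available via
#' `destandardize()` for round-trip checks.
#'
#' @param stream An `imu_stream` (or any data frame containing the 30
#'   channels).
#' @param stats A `channel_stats` from [fit_stats()].
#' @return The stream with standardized channel columns.
#' @export
standardize <- function(stream, stats) {
  stopifnot(inherits(stats, "channel_stats"))
  ch <- gait_channels()
  missing <- setdiff(ch, names(stream))
  if (length(missing))
    stop("stream is missing channel(s): ", paste(missing, collapse = ", "))
  out <- stream
  out[ch] <- sweep(sweep(as.matrix(stream[, ch]), 2, stats$mean), 2,
                   stats$sd, "/")
  out
}

#' @rdname standardize
#' @export
destandardize <- function(stream, stats) {
  stopifnot(inherits(stats, "channel_stats"))
  ch <- gait_channels()
  out <- stream
  out[ch] <- sweep(sweep(as.matrix(stream[, ch]), 2, stats$sd, "*"), 2,
                   stats$mean, "+")
  out
}

#' Instantaneous 30-channel feature vector
#'
#' Returns the channels of one sample in the canonical order, regardless of
#' the column order of the input. This is the per-sample input of the
#' motion-state classifier.
#'
#' @param sample A one-row data frame or named vector holding all 30
#'   channels.
#' @return Named numeric vector of length 30.
#' @export
state_feature_vector <- function(sample) {
  ch <- gait_channels()
  v <- unlist(sample)
  missing <- setdiff(ch, names(v))
  if (length(missing))
    stop("sample is missing channel(s): ", paste(missing, collapse = ", "))
  v[ch]
}

#' Sliding sequence windows for the phase classifier
#'
#' Cuts a standardized stream into windows of `n` consecutive samples with
#' the given stride. Each window's target is the label of its last sample
#' (causal alignment: the classifier sees only the present and the recent
#' past). With stride 1 the number of windows is `length - n + 1`.
#'
#' @param stream Standardized `imu_stream` (or matrix of the 30 channels).
#' @param labels Optional per-sample label vector.
#' @param n Sequence length (default 5).
#' @param stride Window stride (default 1).
#' @return A `sequence_set`: list with `x` (array windows x n x 30),
#'   `y` (targets or `NULL`) and `n`.
#' @export
make_sequences <- function(stream, labels = NULL, n = 5L, stride = 1L) {
  ch <- gait_channels()
  X <- if (is.matrix(stream)) stream else as.matrix(stream[, ch])
  len <- nrow(X)
  if (!is.null(labels)) stopifnot(length(labels) == len)
  if (len < n) {
    warning("stream shorter than sequence length; no sequences produced")
    return(structure(list(x = array(0, c(0, n, ncol(X))), y = NULL, n = n),
                     class = "sequence_set"))
  }
  starts <- seq.int(1L, len - n + 1L, by = stride)
  x <- array(0, c(length(starts), n, ncol(X)),
             dimnames = list(NULL, NULL, colnames(X)))
  for (j in seq_len(n)) x[, j, ] <- X[starts + j - 1L, , drop = FALSE]
  y <- if (!is.null(labels)) labels[starts + n - 1L]
  structure(list(x = x, y = y, n = n), class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("sequence_set:", dim(x$x)[1], "windows of", x$n, "samples x",
      dim(x$x)[3], "channels\n")
  invisible(x)
}

#' Serialize channel statistics to JSON
#'
#' @param stats A `channel_stats`.
#' @param path Output path.
#' @return `read_stats()` returns the `channel_stats`.
#' @export
write_stats <- function(stats, path) {
  jsonlite::write_json(lapply(unclass(stats), as.list), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stats
#' @export
read_stats <- function(path) {
  raw <- jsonlite::read_json(path)
  structure(list(mean = unlist(raw$mean), sd = unlist(raw$sd),
                 constant = unlist(raw$constant)),
            class = "channel_stats")
}
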