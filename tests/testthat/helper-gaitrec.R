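# shared test helpers: tiny stream builders and event-recovery measurement

# an imu_stream whose channel columns are taken from `values` (a named list
# of per-channel vectors); unnamed channels default to zero
make_stream <- function(n, values = list(), sample_rate = 200) {
  ch <- gait_channels()
  df <- data.frame(time_s = (seq_len(n) - 1) / sample_rate)
  for (c_ in ch) df[[c_]] <- if (!is.null(values[[c_]])) values[[c_]] else rep(0, n)
  class(df) <- c("imu_stream", "data.frame")
  attr(df, "sample_rate") <- sample_rate
  df
}

# fraction of interior truth events (index >= min_index) matched by a
# detection within +/- tol samples
recovery_rate <- function(truth, detected, tol = 2, min_index = 3) {
  truth <- truth[truth$sample_index >= min_index, , drop = FALSE]
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    di <- detected$sample_index[detected$event == truth$event[i] &
                                  detected$side == truth$side[i]]
    any(abs(di - truth$sample_index[i]) <= tol)
  }, logical(1))
  mean(hit)
}

# timeline data frame from phase labels and 0-based indices
timeline_of <- function(phases, indices) {
  df <- data.frame(sample_index = as.integer(indices),
                   side = substr(phases, 1, 1),
                   event = sub("^[LR]-", "", phases))
  class(df) <- c("event_timeline", "data.frame")
  df
}

# the six phase labels of k perfect cycles in canonical order, with indices
perfect_timeline <- function(k, cycle_samples = 200) {
  frac <- c(`L-HS` = 0, `R-TO` = 0.1, `R-HMax` = 0.35, `R-HS` = 0.5,
            `L-TO` = 0.6, `L-HMax` = 0.85)
  phases <- rep(names(frac), k)
  idx <- as.integer(outer(frac * cycle_samples, (0:(k - 1)) * cycle_samples,
                          "+"))
  timeline_of(phases, idx)
}

# exhaustive longest order-consistent subsequence size (oracle for the DP
# retention in build_timeline); events given as (index, phase-code 1..6)
oracle_longest_valid <- function(idx, code) {
  n <- length(idx)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    if (length(sel) > 1) {
      for (j in 2:length(sel)) {
        a <- sel[j - 1]; b <- sel[j]
        if (!(idx[b] > idx[a]) || code[b] != (code[a] %% 6L) + 1L) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) best <- length(sel)
  }
  best
}
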