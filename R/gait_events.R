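#' Rule-based gait-event detection from IMU channels
#'
#' Three detection rules segment the gait cycle online from gyroscope
#' channels alone. Heel strike (HS) is the falling zero crossing of the
#' foot sagittal angular velocity (maximum dorsiflexion); toe off (TO) is
#' the sharp negative trough of the same channel (maximum plantar-flexion
#' rate at push-off); maximum hip flexion (HMax) is the falling zero
#' crossing of the thigh sagittal angular velocity (the hip angle's
#' derivative vanishes at its maximum).
#'
#' All indices are 0-based sample indices. The event sample is the first
#' sample at or past zero: a falling crossing is reported at `k+1` when
#' `x[k] > 0 >= x[k+1]` (0-based `k`).
#'
#' @param x Numeric channel (rad/s).
#' @param min_separation Minimum samples between retained events
#'   (refractory window); a sensible default is a quarter of the nominal
#'   cycle period.
#' @return Integer vector of 0-based sample indices, sorted ascending.
#' @name gait_event_detectors
NULL

#' @rdname gait_event_detectors
#' @param tol Numerical zero: values within `tol` of zero count as
#'   non-positive, so a sample that is zero up to floating-point error is
#'   the event sample.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1 / 200)[1:400]
#' detect_hs(sin(2 * pi * t), min_separation = 50)  # 100, 300
detect_hs <- function(x, min_separation = 1L, tol = 1e-9) {
  n <- length(x)
  if (n < 2) return(integer(0))
  k <- which(x[-n] > tol & x[-1] <= tol)  # 1-based k -> 0-based index k
  debounce_first(as.integer(k), min_separation)
}

#' @rdname gait_event_detectors
#' @export
detect_hmax <- function(x, min_separation = 1L, tol = 1e-9) {
  detect_hs(x, min_separation, tol)
}

#' @rdname gait_event_detectors
#' @param min_prominence Minimum trough prominence (rad/s). Defaults to
#'   three times a median-absolute-deviation noise estimate of the channel.
#' @param smooth Odd moving-average window applied before trough search
#'   (1 = none).
#' @export
detect_to <- function(x, min_separation = 1L, min_prominence = NULL,
                      smooth = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  if (is.null(min_prominence)) min_prominence <- 3 * estimate_noise_sigma(x)
  if (smooth > 1L) {
    x <- stats::filter(x, rep(1 / smooth, smooth), sides = 2)
    x[is.na(x)] <- 0
  }
  xi <- as.numeric(x)
  cand <- which(diff(sign(diff(xi))) > 0) + 1L  # local minima, 1-based
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) trough_prominence(xi, i), numeric(1))
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))
  # deepest-first retention under the refractory window
  cand <- cand[order(xi[cand])]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_separation))
      kept <- c(kept, i)
  }
  sort(kept) - 1L  # 0-based
}

# prominence of a local minimum: rise to the lower of the two enclosing
# maxima, walking outward until a sample deeper than the trough (or the
# boundary) is met
trough_prominence <- function(x, i) {
  left <- x[seq_len(i - 1L)]
  below <- which(left < x[i])
  lo <- if (length(below)) max(below) + 1L else 1L
  rise_l <- max(left[lo:(i - 1L)] , -Inf) - x[i]
  right <- x[(i + 1L):length(x)]
  below <- which(right < x[i])
  hi <- if (length(below)) min(below) - 1L else length(right)
  rise_r <- max(right[seq_len(hi)], -Inf) - x[i]
  min(rise_l, rise_r)
}

debounce_first <- function(idx, min_separation) {
  if (length(idx) < 2 || min_separation <= 1) return(idx)
  kept <- idx[1]
  for (i in idx[-1]) if (i - kept[length(kept)] >= min_separation) kept <- c(kept, i)
  kept
}

estimate_noise_sigma <- function(x) {
  stats::mad(diff(x)) / sqrt(2)
}

# ---- timeline assembly ---------------------------------------------------

phase_successor <- function(p) {
  cls <- phase_classes()
  cls[(match(p, cls) %% 6L) + 1L]
}

phase_predecessor <- function(p) {
  cls <- phase_classes()
  cls[((match(p, cls) - 2L) %% 6L) + 1L]
}

#' Assemble an event timeline from per-side detections
#'
#' Merges the six per-event index lists, sorts them, and retains the
#' longest subsequence consistent with the canonical cyclic order
#' L-HS, R-TO, R-HMax, R-HS, L-TO, L-HMax (truncation at bout boundaries
#' allowed, strictly increasing indices). The retained set is computed by
#' dynamic programming over the cyclic successor chain, so it is the
#' maximum-cardinality order-consistent subsequence; dropped events are
#' reported.
#'
#' @param per_side_events Named list of integer index vectors; names must
#'   be the six phase labels (`phase_classes()`).
#' @return List with `timeline` (an `event_timeline`), `dropped` (data
#'   frame of discarded events) and `n_dropped`.
#' @export
build_timeline <- function(per_side_events) {
  cls <- phase_classes()
  missing <- setdiff(cls, names(per_side_events))
  if (length(missing))
    stop("per_side_events must be named by all six phases; missing: ",
         paste(missing, collapse = ", "))
  ev <- do.call(rbind, lapply(cls, function(p) {
    idx <- per_side_events[[p]]
    if (!length(idx)) return(NULL)
    data.frame(sample_index = as.integer(idx),
               side = substr(p, 1, 1),
               event = sub("^[LR]-", "", p),
               phase = p)
  }))
  if (is.null(ev) || !nrow(ev)) {
    warning("no events supplied; timeline is empty")
    tl <- empty_timeline()
    return(list(timeline = tl, dropped = as.data.frame(tl), n_dropped = 0L))
  }
  ev <- ev[order(ev$sample_index, match(ev$phase, cls)), , drop = FALSE]
  keep <- longest_ordered_subsequence(ev$sample_index, match(ev$phase, cls))
  tl <- ev[keep, c("sample_index", "side", "event"), drop = FALSE]
  rownames(tl) <- NULL
  class(tl) <- c("event_timeline", "data.frame")
  dropped <- ev[setdiff(seq_len(nrow(ev)), keep),
                c("sample_index", "side", "event"), drop = FALSE]
  rownames(dropped) <- NULL
  if (!nrow(tl)) warning("all events dropped; timeline is empty")
  list(timeline = tl, dropped = dropped, n_dropped = nrow(dropped))
}

empty_timeline <- function() {
  tl <- data.frame(sample_index = integer(0), side = character(0),
                   event = character(0))
  class(tl) <- c("event_timeline", "data.frame")
  tl
}

# indices (into the sorted event list) of a maximum-length subsequence with
# strictly increasing sample_index whose phase codes follow the cyclic
# successor chain; ties in length resolved toward earlier events
longest_ordered_subsequence <- function(idx, phase_code) {
  n <- length(idx)
  len <- integer(n)
  prev <- integer(n)
  # best[p] = position of the current best chain ending in phase p
  best_len <- integer(6)
  best_pos <- integer(6)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && idx[j + 1L] == idx[i]) j <- j + 1L
    # process the tie-group [i, j] against state built from indices < idx[i]
    for (k in i:j) {
      p <- phase_code[k]
      pp <- ((p - 2L) %% 6L) + 1L  # predecessor phase
      if (best_len[pp] > 0L) {
        len[k] <- best_len[pp] + 1L
        prev[k] <- best_pos[pp]
      } else {
        len[k] <- 1L
        prev[k] <- 0L
      }
    }
    for (k in i:j) {
      p <- phase_code[k]
      if (len[k] > best_len[p]) { best_len[p] <- len[k]; best_pos[p] <- k }
    }
    i <- j + 1L
  }
  if (!n) return(integer(0))
  end <- which.max(len)
  out <- integer(len[end])
  k <- end
  for (m in seq(len[end], 1L)) { out[m] <- k; k <- prev[k] }
  out
}

#' Check a timeline against the canonical cyclic event order
#'
#' Walks the timeline keeping an expectation equal to the cyclic successor
#' of the last accepted event. An event is accepted when it matches the
#' expectation or skips ahead of it by at most half a cycle (three phases)
#' — a forward skip reads as missed detections, not disorder. An event
#' that falls cyclically behind the expectation (a duplicate or an
#' out-of-place event), or whose sample index does not increase, is
#' reported as a violation and skipped. An empty report means the timeline
#' is valid.
#'
#' @param timeline An `event_timeline`.
#' @return Data frame with columns `position`, `expected`, `found`
#'   (0 rows when valid).
#' @export
validate_event_order <- function(timeline) {
  viol <- data.frame(position = integer(0), expected = character(0),
                     found = character(0))
  if (!nrow(timeline)) return(viol)
  cls <- phase_classes()
  ph <- phase_of(timeline$side, timeline$event)
  idx <- timeline$sample_index
  expect <- NULL
  last_idx <- -Inf
  for (i in seq_along(ph)) {
    skip <- if (is.null(expect)) 0L
            else (match(ph[i], cls) - match(expect, cls)) %% 6L
    if (skip <= 3L && idx[i] > last_idx) {
      expect <- phase_successor(ph[i])
      last_idx <- idx[i]
    } else {
      viol <- rbind(viol, data.frame(
        position = i,
        expected = if (is.null(expect)) "" else expect,
        found = ph[i]))
    }
  }
  viol
}

#' Per-sample gait-phase labels from an event timeline
#'
#' Every sample from one event up to (but excluding) the next receives the
#' earlier event's phase class; samples before the first event receive the
#' class cyclically preceding it.
#'
#' @param timeline A valid, non-empty `event_timeline`.
#' @param n_samples Total samples to label; must exceed the last event
#'   index.
#' @return Character vector of length `n_samples` over `phase_classes()`.
#' @export
label_phases <- function(timeline, n_samples) {
  if (!nrow(timeline)) stop("cannot label phases from an empty timeline")
  if (n_samples <= max(timeline$sample_index))
    stop("n_samples must exceed the last event index")
  ph <- phase_of(timeline$side, timeline$event)
  idx <- timeline$sample_index  # 0-based
  labels <- character(n_samples)
  if (idx[1] > 0)
    labels[seq_len(idx[1])] <- phase_predecessor(ph[1])
  bounds <- c(idx, n_samples)
  for (i in seq_along(ph))
    labels[(bounds[i] + 1L):bounds[i + 1L]] <- ph[i]
  labels
}

#' Detect all six events of a two-leg stream and label its phases
#'
#' Convenience wrapper: runs the HS/TO/HMax detectors on both feet and
#' thighs, assembles the timeline and (optionally) the per-sample phase
#' labels.
#'
#' @param stream An `imu_stream`.
#' @param nominal_period Nominal cycle period in seconds, used for the
#'   refractory window (a quarter cycle).
#' @param with_labels Also compute per-sample phase labels.
#' @return List with `timeline`, `dropped`, and `labels` (when requested).
#' @export
label_stream <- function(stream, nominal_period = 1.0, with_labels = TRUE) {
  fs <- attr(stream, "sample_rate")
  if (is.null(fs)) fs <- 1 / stats::median(diff(stream$time_s))
  sep <- max(2L, round(0.25 * nominal_period * fs))
  per <- list(
    `L-HS` = detect_hs(stream$foot_l_gz, sep),
    `R-TO` = detect_to(stream$foot_r_gz, sep),
    `R-HMax` = detect_hmax(stream$thigh_r_gz, sep),
    `R-HS` = detect_hs(stream$foot_r_gz, sep),
    `L-TO` = detect_to(stream$foot_l_gz, sep),
    `L-HMax` = detect_hmax(stream$thigh_l_gz, sep)
  )
  bt <- build_timeline(per)
  out <- list(timeline = bt$timeline, dropped = bt$dropped)
  if (with_labels && nrow(bt$timeline))
    out$labels <- label_phases(bt$timeline, nrow(stream))
  out
}
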