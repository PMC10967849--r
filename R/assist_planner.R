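#' Assistance-force profile for one swing
#'
#' The hip-flexion assistance force applied between toe off (window start)
#' and heel strike (window end), peaking at maximum hip flexion. The
#' default `"product"` form is
#' `F(t) = A * sin(pi*t/Ta + alpha) * sin(pi*t/Ta) + f` on `t in [0, Ta]`
#' (t relative to the window start), clamped below at zero and zero outside
#' the window; it vanishes at the window start and its peak location is set
#' by the phase-shift factor `alpha`. A `"simple"` single-sinusoid form
#' `A * sin(pi*t/Ta + alpha) + f` is available as a configuration switch.
#'
#' @param A Force magnitude (N, >= 0 for assistance).
#' @param Ta Swing period (s, > 0): the TO-to-HS interval.
#' @param alpha Phase-shift factor (rad).
#' @param f Force offset (N) keeping the belt taut (default 2).
#' @param t_start Absolute window start time (s), i.e. the TO event.
#' @param form `"product"` (default) or `"simple"`.
#' @return An `assist_profile` with absolute `t_start`, `t_peak`, `t_end`.
#' @export
assist_profile <- function(A, Ta, alpha = 0, f = 2, t_start = 0,
                           form = c("product", "simple")) {
  form <- match.arg(form)
  if (Ta <= 0) stop("Ta (swing period) must be positive")
  structure(list(A = A, Ta = Ta, alpha = alpha, f = f,
                 t_start = t_start, t_peak = t_start + peak_time(Ta, alpha, form),
                 t_end = t_start + Ta, form = form),
            class = "assist_profile")
}

# peak location of the profile on [0, Ta]
peak_time <- function(Ta, alpha, form) {
  t <- switch(form,
              product = Ta * (pi - alpha) / (2 * pi),
              simple = Ta * (pi / 2 - alpha) / pi)
  min(max(t, 0), Ta)
}

# phase shift placing the peak at t_peak_rel (relative to window start)
solve_alpha <- function(Ta, t_peak_rel, form = "product") {
  if (t_peak_rel <= 0 || t_peak_rel >= Ta)
    stop("peak time must lie strictly inside the swing window")
  switch(form,
         product = pi - 2 * pi * t_peak_rel / Ta,
         simple = pi / 2 - pi * t_peak_rel / Ta)
}

#' Evaluate the assistance force
#'
#' @param profile An [assist_profile()].
#' @param t Time (s) relative to the window start; vectorized.
#' @return Force in N: the profile value inside `[0, Ta]` (never below
#'   zero), 0 outside.
#' @export
#' @examples
#' p <- assist_profile(A = 40, Ta = 0.4, alpha = 0, f = 0)
#' force_at(p, 0.2)  # = A at mid-swing
force_at <- function(profile, t) {
  x <- pi * t / profile$Ta
  F_ <- switch(profile$form,
               product = profile$A * sin(x + profile$alpha) * sin(x) + profile$f,
               simple = profile$A * sin(x + profile$alpha) + profile$f)
  F_ <- pmax(F_, 0)
  F_[t < 0 | t > profile$Ta] <- 0
  F_
}

#' Sampled force trajectory
#'
#' @param profile An [assist_profile()].
#' @param sample_rate Sampling rate, Hz.
#' @return Data frame with absolute `time_s` and `force_N` over the window.
#' @export
sample_profile <- function(profile, sample_rate = 200) {
  t <- seq(0, profile$Ta, by = 1 / sample_rate)
  data.frame(time_s = profile$t_start + t, force_N = force_at(profile, t))
}

#' Predict the next swing's assistance times from the previous cycle
#'
#' Constant-cadence prediction: the upcoming TO, HMax and HS times are the
#' previous cycle's event times advanced by the previous cycle period; the
#' swing period `Ta` is the previous TO-to-HS interval, and `alpha` is
#' solved so the profile peak falls exactly at the predicted HMax (closed
#' form for both profile shapes; the grid-checked placement error is below
#' 1e-3 * Ta).
#'
#' @param previous List with the previous cycle's event times in seconds —
#'   `TO`, `HMax`, `HS` (must satisfy TO < HMax < HS) — and `period`, the
#'   previous cycle duration.
#' @param A,f,form Profile parameters passed through to
#'   [assist_profile()].
#' @return An `assist_profile` anchored at the predicted events, with the
#'   predicted times in `t_start`, `t_peak`, `t_end`.
#' @export
predict_assist_times <- function(previous, A = 40, f = 2, form = "product") {
  with(previous, {
    if (!(TO < HMax && HMax < HS))
      stop("previous cycle must satisfy TO < HMax < HS")
    if (period <= 0) stop("period must be positive")
    Ta <- HS - TO
    alpha <- solve_alpha(Ta, HMax - TO, form)
    assist_profile(A = A, Ta = Ta, alpha = alpha, f = f,
                   t_start = TO + period, form = form)
  })
}

# per-leg swing table (TO -> HMax -> HS triples) from an event timeline
leg_swings <- function(timeline, side, sample_rate) {
  ev <- timeline[timeline$side == side, , drop = FALSE]
  ev <- ev[order(ev$sample_index), , drop = FALSE]
  out <- NULL
  i <- 1L
  while (i <= nrow(ev) - 2L) {
    if (ev$event[i] == "TO" && ev$event[i + 1L] == "HMax" &&
        ev$event[i + 2L] == "HS") {
      out <- rbind(out, data.frame(
        to_idx = ev$sample_index[i], hs_idx = ev$sample_index[i + 2L],
        TO = ev$sample_index[i] / sample_rate,
        HMax = ev$sample_index[i + 1L] / sample_rate,
        HS = ev$sample_index[i + 2L] / sample_rate))
      i <- i + 3L
    } else i <- i + 1L
  }
  out
}

#' Plan state-gated assistance profiles for a labeled bout
#'
#' Emits one profile per completed swing (TO, HMax, HS triple) of each leg,
#' anchored at the swing's events: the window starts at TO, ends at HS, and
#' `alpha` places the peak at HMax. A swing receives assistance only when
#' the majority motion state over its samples is level walking (`LW`);
#' swings in any other state get a zero-force profile (`A = 0, f = 0`) for
#' safety.
#'
#' @param state_stream Per-sample motion-state labels, time-aligned with
#'   the timeline's sample indices.
#' @param timeline An `event_timeline`.
#' @param A,f Profile parameters for assisted swings.
#' @param sample_rate Hz (default 200).
#' @param form Profile shape, see [assist_profile()].
#' @return An `assist_plan` data frame: `leg, cycle_index, t_start_s,
#'   t_peak_s, t_end_s, A_N, f_N, alpha_rad, Ta_s`.
#' @export
plan_assistance <- function(state_stream, timeline, A = 40, f = 2,
                            sample_rate = 200, form = "product") {
  rows <- NULL
  if (nrow(timeline) == 0)
    return(structure(empty_plan(), class = c("assist_plan", "data.frame")))
  for (side in c("L", "R")) {
    sw <- leg_swings(timeline, side, sample_rate)
    if (is.null(sw)) next
    for (k in seq_len(nrow(sw))) {
      states <- state_stream[(sw$to_idx[k] + 1L):(sw$hs_idx[k] + 1L)]
      lw <- majority_label(states) == "LW"
      Ta <- sw$HS[k] - sw$TO[k]
      alpha <- solve_alpha(Ta, sw$HMax[k] - sw$TO[k], form)
      rows <- rbind(rows, data.frame(
        leg = side, cycle_index = k,
        t_start_s = sw$TO[k], t_peak_s = sw$TO[k] + peak_time(Ta, alpha, form),
        t_end_s = sw$HS[k],
        A_N = if (lw) A else 0, f_N = if (lw) f else 0,
        alpha_rad = alpha, Ta_s = Ta))
    }
  }
  if (is.null(rows)) rows <- empty_plan()
  rows <- rows[order(rows$leg, rows$cycle_index), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, class = c("assist_plan", "data.frame"))
}

empty_plan <- function() {
  data.frame(leg = character(0), cycle_index = integer(0),
             t_start_s = numeric(0), t_peak_s = numeric(0),
             t_end_s = numeric(0), A_N = numeric(0), f_N = numeric(0),
             alpha_rad = numeric(0), Ta_s = numeric(0))
}

majority_label <- function(x) {
  tb <- sort(table(x), decreasing = TRUE)
  names(tb)[1]
}

#' @rdname plan_assistance
#' @param plan An `assist_plan`.
#' @param path CSV path.
#' @export
write_plan <- function(plan, path) {
  utils::write.csv(as.data.frame(plan), path, row.names = FALSE)
  invisible(path)
}
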