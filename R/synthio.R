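#' Specification of a synthetic gait cycle
#'
#' Defines the periodic structure from which two-leg IMU gait signals are
#' synthesized. Each leg runs the same cycle shifted by `inter_leg_offset`
#' (half a cycle for symmetric gait). Within its own cycle a leg passes three
#' events: heel strike (HS), toe off (TO) and maximum hip flexion (HMax),
#' placed at the given fractions of the cycle. After applying the inter-leg
#' offset the six events must fall in the canonical global order
#' L-HS, R-TO, R-HMax, R-HS, L-TO, L-HMax.
#'
#' @param cycle_period Cycle duration in seconds (> 0).
#' @param event_fractions Named numeric vector `c(HS=, TO=, HMax=)` of
#'   own-leg cycle fractions in `[0, 1)`. Defaults place HS at 0, TO at 0.60
#'   and HMax at 0.85, standard level-walking phenomenology.
#' @param inter_leg_offset Fraction of a cycle by which the right leg lags
#'   the left (default 0.5).
#' @param noise_sigma_gyro Additive white-noise standard deviation on
#'   gyroscope channels, rad/s.
#' @param noise_sigma_acc Additive white-noise standard deviation on
#'   accelerometer channels, m/s^2.
#' @param sample_rate Sampling frequency in Hz (default 200).
#' @param seed Integer seed controlling the noise realization.
#' @return An object of class `gait_cycle_spec`.
#' @export
#' @examples
#' spec <- gait_cycle_spec(noise_sigma_gyro = 0)
#' sim <- generate_cycle(spec, n_cycles = 2)
#' head(sim$timeline)
gait_cycle_spec <- function(cycle_period = 1.0,
                            event_fractions = c(HS = 0.0, TO = 0.60, HMax = 0.85),
                            inter_leg_offset = 0.5,
                            noise_sigma_gyro = 0.05,
                            noise_sigma_acc = 0.10,
                            sample_rate = 200,
                            seed = 1L) {
  stopifnot(is.numeric(cycle_period), cycle_period > 0)
  if (!all(c("HS", "TO", "HMax") %in% names(event_fractions)))
    stop("event_fractions must be named with HS, TO and HMax")
  ef <- event_fractions[c("HS", "TO", "HMax")]
  if (any(ef < 0 | ef >= 1)) stop("event fractions must lie in [0, 1)")
  if (anyDuplicated(ef)) stop("event fractions must be distinct")
  if (sample_rate * cycle_period < 50)
    stop("sample_rate * cycle_period must be >= 50 to place six events")
  spec <- structure(list(
    cycle_period = cycle_period,
    event_fractions = ef,
    inter_leg_offset = inter_leg_offset,
    noise_sigma_gyro = noise_sigma_gyro,
    noise_sigma_acc = noise_sigma_acc,
    sample_rate = sample_rate,
    seed = as.integer(seed)
  ), class = "gait_cycle_spec")
  ord <- event_global_order(spec)
  canon <- phase_classes()
  if (!identical(ord, canon))
    stop("event fractions violate the canonical event order: got ",
         paste(ord, collapse = " -> "), "; expected ",
         paste(canon, collapse = " -> "))
  spec
}

# global cycle fractions of the six events, keyed by phase label
event_global_fractions <- function(spec) {
  ef <- spec$event_fractions
  off <- spec$inter_leg_offset
  gf <- c(
    `L-HS` = unname(ef["HS"]),
    `L-TO` = unname(ef["TO"]),
    `L-HMax` = unname(ef["HMax"]),
    `R-HS` = unname((ef["HS"] + off) %% 1),
    `R-TO` = unname((ef["TO"] + off) %% 1),
    `R-HMax` = unname((ef["HMax"] + off) %% 1)
  )
  gf
}

event_global_order <- function(spec) {
  gf <- event_global_fractions(spec)
  ord <- names(sort(gf))
  # rotate so L-HS leads, preserving cyclic order
  i <- match("L-HS", ord)
  c(ord[i:length(ord)], ord[seq_len(i - 1L)])
}

# ---- waveform primitives -------------------------------------------------
#
# Foot gyro Z (sagittal): a falling zero crossing marks HS, a sharp negative
# trough (narrow Gaussian dip superimposed on a negative stance/swing arc)
# marks TO, mimicking the brief plantar-flexion rate spike at push-off. The
# arc keeps the signal negative around TO so the dip introduces no extra
# zero crossings, and the positive swing lobe is square-root shaped so the
# signal enters and leaves zero steeply — the crossing stays localized
# under sensor noise.
foot_gyro_wave <- function(u, hs_frac, to_frac,
                           amp = 6.0, dip = 4.0, dip_width = 0.012) {
  v <- (u - hs_frac) %% 1
  d <- (to_frac - hs_frac) %% 1
  w <- min(d + 0.15, 0.95)  # negative arc spans [0, w) of the shifted cycle
  y <- ifelse(v < w,
              -amp * sin(pi * v / w),
              0.8 * amp * sqrt(pmax(sin(pi * (v - w) / (1 - w)), 0)))
  dv <- pmin(abs(v - d), 1 - abs(v - d))  # circular distance to TO
  y - dip * exp(-dv^2 / (2 * dip_width^2))
}

# Thigh gyro Z: hip flexion angular velocity, a sinusoid whose falling zero
# crossing coincides with the hip-angle maximum (HMax).
thigh_gyro_wave <- function(u, hmax_frac, amp = 3.0) {
  -amp * sin(2 * pi * (u - hmax_frac))
}

GRAVITY <- 9.81

# per-channel base oscillation amplitudes for the generic channels
base_amplitudes <- function() {
  ch <- gait_channels()
  amp <- setNames(rep(1.2, length(ch)), ch)
  amp[grepl("_a[xyz]$", ch)] <- 2.0
  amp[c("waist_gx", "waist_gy", "waist_gz")] <- 0.3
  # foot/thigh gz are produced by the event-bearing waveforms
  amp[c("foot_l_gz", "foot_r_gz", "thigh_l_gz", "thigh_r_gz")] <- 0
  amp
}

channel_phases <- function() {
  ch <- gait_channels()
  setNames(2 * pi * ((seq_along(ch) * 0.381966) %% 1), ch)
}

#' Per-state channel signatures
#'
#' Each motion state modulates the baseline level-walking signal by a
#' per-channel multiplicative gain on the oscillatory component and an
#' additive offset. Standing zeroes the oscillation; stairs shift the waist
#' vertical acceleration; slopes shift the waist fore-aft acceleration;
#' turning and steering bias the waist yaw rate (and pitch rate for
#' steering). Signatures of distinct states differ in at least one channel
#' by more than three noise standard deviations, so the classes are
#' learnable at the default noise levels.
#'
#' @param state One of [motion_states()].
#' @return List with numeric vectors `gain` and `offset` (length 30, named
#'   by channel).
#' @export
state_signature <- function(state) {
  states <- motion_states()
  if (!state %in% states)
    stop("unknown state '", state, "'; valid states: ",
         paste(states, collapse = ", "))
  ch <- gait_channels()
  gain <- setNames(rep(1, length(ch)), ch)
  offset <- setNames(rep(0, length(ch)), ch)
  thigh_gy <- c("thigh_l_gy", "thigh_r_gy")
  switch(state,
    SD = { gain[] <- 0 },
    LW = { },
    US = { offset["waist_az"] <- 0.8;  gain[thigh_gy] <- 1.5 },
    DS = { offset["waist_az"] <- -0.8; gain[thigh_gy] <- 0.7 },
    USL = { offset["waist_ax"] <- 1.5 },
    DSL = { offset["waist_ax"] <- -1.5 },
    TL = { offset["waist_gz"] <- 0.8 },
    TR = { offset["waist_gz"] <- -0.8 },
    LS = { offset["waist_gz"] <- 0.4; offset["waist_gy"] <- 0.4 },
    RS = { offset["waist_gz"] <- -0.4; offset["waist_gy"] <- -0.4 }
  )
  list(gain = gain, offset = offset)
}

# ---- generation ----------------------------------------------------------

#' Generate a synthetic two-leg IMU walking bout
#'
#' Synthesizes a 30-channel IMU stream of `n_cycles` gait cycles together
#' with the ground-truth event timeline. The noiseless foot gyro Z channel
#' of each leg has a falling zero crossing exactly at each HS truth index
#' and a sharp negative trough at each TO truth index; the thigh gyro Z
#' channel crosses zero (falling) at each HMax truth index. Remaining
#' channels carry cycle-locked sinusoids modulated by the state signature.
#'
#' @param spec A [gait_cycle_spec()].
#' @param n_cycles Number of gait cycles (>= 1).
#' @param state Motion state whose signature is applied (default `"LW"`).
#' @param gain_mult Optional per-channel multiplier (length 30) emulating
#'   subject-specific amplitude variation.
#' @return List with `stream` (an `imu_stream` data frame: `time_s` plus the
#'   30 channels) and `timeline` (an `event_timeline` data frame with
#'   columns `sample_index`, `side`, `event`, 0-based sample indices).
#' @export
generate_cycle <- function(spec, n_cycles, state = "LW", gain_mult = NULL) {
  stopifnot(inherits(spec, "gait_cycle_spec"), n_cycles >= 1)
  sig <- state_signature(state)
  ch <- gait_channels()
  if (is.null(gain_mult)) gain_mult <- setNames(rep(1, length(ch)), ch)

  fs <- spec$sample_rate
  T_ <- spec$cycle_period
  n <- round(n_cycles * T_ * fs)
  t <- (seq_len(n) - 1L) / fs
  u_l <- (t / T_) %% 1
  u_r <- (t / T_ - spec$inter_leg_offset) %% 1

  ef <- spec$event_fractions
  amp <- base_amplitudes()
  phs <- channel_phases()

  X <- matrix(0, nrow = n, ncol = length(ch), dimnames = list(NULL, ch))
  for (c_ in ch) {
    sensor <- sub("_(g|a)[xyz]$", "", c_)
    u <- if (sensor %in% c("thigh_r", "foot_r")) u_r else u_l
    g <- sig$gain[c_] * gain_mult[c_]
    base <-
      if (c_ %in% c("foot_l_gz", "foot_r_gz")) {
        foot_gyro_wave(u, ef["HS"], ef["TO"])
      } else if (c_ %in% c("thigh_l_gz", "thigh_r_gz")) {
        thigh_gyro_wave(u, ef["HMax"])
      } else {
        amp[c_] * sin(2 * pi * u + phs[c_])
      }
    X[, c_] <- g * base + sig$offset[c_]
    if (grepl("_az$", c_)) X[, c_] <- X[, c_] + GRAVITY
  }

  # additive sensor noise, reproducible from spec$seed
  if (spec$noise_sigma_gyro > 0 || spec$noise_sigma_acc > 0) {
    X <- X + with_local_seed(spec$seed, {
      sig_ch <- ifelse(grepl("_g[xyz]$", ch),
                       spec$noise_sigma_gyro, spec$noise_sigma_acc)
      matrix(stats::rnorm(n * length(ch)), n, length(ch)) %*% diag(sig_ch)
    })
  }

  stream <- data.frame(time_s = t, X, check.names = FALSE)
  class(stream) <- c("imu_stream", "data.frame")
  attr(stream, "sample_rate") <- fs

  timeline <- truth_timeline(spec, n_cycles, n)
  list(stream = stream, timeline = timeline)
}

truth_timeline <- function(spec, n_cycles, n_samples) {
  gf <- event_global_fractions(spec)
  fs <- spec$sample_rate
  T_ <- spec$cycle_period
  rows <- do.call(rbind, lapply(seq_len(n_cycles) - 1L, function(k) {
    idx <- round((k + gf) * T_ * fs)
    data.frame(sample_index = as.integer(idx),
               side = substr(names(gf), 1, 1),
               event = sub("^[LR]-", "", names(gf)))
  }))
  rows <- rows[rows$sample_index < n_samples, , drop = FALSE]
  rows <- rows[order(rows$sample_index), , drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("event_timeline", "data.frame")
  rows
}

# evaluate expr with a temporary RNG seed, restoring global RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a labeled multi-subject, multi-state dataset
#'
#' Builds one walking bout per subject and state, applying per-subject
#' variation: a multiplicative jitter of up to +/-10% on the cycle period
#' and on each channel gain, drawn reproducibly from the top-level seed via
#' a counter scheme (`stream seed = (seed * 7919 + subject * 131 +
#' state index) mod 2^31 - 1`), so any subject subset regenerates
#' identically.
#'
#' @param states Character vector, subset of [motion_states()].
#' @param n_subjects Number of subjects (>= 1).
#' @param cycles_per_state Gait cycles per bout.
#' @param seed Top-level integer seed.
#' @param spec Base [gait_cycle_spec()] (its own seed is ignored).
#' @return A `labeled_dataset`: list with `streams`, `state` (per stream),
#'   `subject` (per stream), `labels` (per-sample motion-state vector per
#'   stream) and `event_truth` (ground-truth timeline per stream).
#' @export
generate_dataset <- function(states, n_subjects, cycles_per_state,
                             seed = 1L, spec = gait_cycle_spec()) {
  bad <- setdiff(states, motion_states())
  if (length(bad))
    stop("unknown state(s) ", paste(bad, collapse = ", "),
         "; valid states: ", paste(motion_states(), collapse = ", "))
  stopifnot(n_subjects >= 1, cycles_per_state >= 1)
  ch <- gait_channels()
  streams <- list(); st <- character(); subj <- integer()
  labels <- list(); truth <- list()
  mod <- .Machine$integer.max
  for (s in seq_len(n_subjects)) {
    subj_seed <- (seed * 7919 + s * 131) %% mod
    jit <- with_local_seed(subj_seed, {
      list(period = stats::runif(1, 0.9, 1.1),
           gains = setNames(stats::runif(length(ch), 0.9, 1.1), ch))
    })
    for (k in seq_along(states)) {
      state <- states[k]
      stream_seed <- (seed * 7919 + s * 131 + match(state, motion_states())) %% mod
      sp <- spec
      sp$cycle_period <- spec$cycle_period * jit$period
      sp$seed <- as.integer(stream_seed)
      sim <- generate_cycle(sp, cycles_per_state, state = state,
                            gain_mult = jit$gains)
      streams[[length(streams) + 1L]] <- sim$stream
      st <- c(st, state)
      subj <- c(subj, s)
      labels[[length(labels) + 1L]] <- rep(state, nrow(sim$stream))
      truth[[length(truth) + 1L]] <- sim$timeline
    }
  }
  structure(list(streams = streams, state = st, subject = subj,
                 labels = labels, event_truth = truth),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", length(x$streams), "streams,",
      length(unique(x$subject)), "subjects, states:",
      paste(unique(x$state), collapse = " "), "\n")
  invisible(x)
}
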