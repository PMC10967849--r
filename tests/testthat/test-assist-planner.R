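test_that("the force profile obeys its closed-form anchors", {
  p <- assist_profile(A = 40, Ta = 0.4, alpha = 0, f = 0)
  expect_equal(force_at(p, 0), 0)
  expect_equal(force_at(p, 0.2), 40)            # peak at mid-swing
  expect_equal(force_at(p, 0.4), 0, tolerance = 1e-12)
  expect_equal(force_at(p, -0.1), 0)            # zero outside the window
  expect_equal(force_at(p, 0.5), 0)
  pc <- assist_profile(A = 0, Ta = 0.4, alpha = 0.3, f = 2.5)
  tt <- seq(0, 0.4, by = 0.01)
  expect_true(all(force_at(pc, tt) == 2.5))
  expect_error(assist_profile(A = 1, Ta = 0), "positive")
})

test_that("profile peak location matches a brute-force grid search", {
  p <- assist_profile(A = 10, Ta = 0.4, alpha = 0.2, f = 1)
  tt <- seq(0, 0.4, length.out = 1000)
  grid_peak <- tt[which.max(force_at(p, tt))]
  expect_lt(abs((p$t_peak - p$t_start) - grid_peak), 0.4 / 999 + 1e-12)
  # simple single-sinusoid form
  ps <- assist_profile(A = 10, Ta = 0.4, alpha = 0.2, f = 1,
                       form = "simple")
  grid_peak_s <- tt[which.max(force_at(ps, tt))]
  expect_lt(abs((ps$t_peak - ps$t_start) - grid_peak_s), 0.4 / 999 + 1e-12)
})

test_that("solved alpha places the peak at HMax within 1e-3 * Ta", {
  for (frac in c(0.3, 0.5, 0.62, 0.8)) {
    prev <- list(TO = 0.6, HMax = 0.6 + frac * 0.4, HS = 1.0, period = 1)
    p <- predict_assist_times(prev)
    tt <- seq(0, p$Ta, by = 1e-4 * p$Ta)
    grid_peak <- tt[which.max(force_at(p, tt))]
    expect_lt(abs(grid_peak - (p$t_peak - p$t_start)), 1e-3 * p$Ta)
    expect_equal(p$t_peak - p$t_start, frac * 0.4, tolerance = 1e-9)
  }
})

test_that("the profile never goes negative for non-negative A and f", {
  set.seed(2)
  for (rep_ in 1:20) {
    p <- assist_profile(A = runif(1, 0, 60), Ta = runif(1, 0.2, 0.6),
                        alpha = runif(1, -2, 2), f = runif(1, 0, 5))
    tt <- seq(-0.1, p$Ta + 0.1, length.out = 500)
    expect_true(all(force_at(p, tt) >= 0))
  }
})

test_that("constant cadence predicts the next cycle exactly", {
  prev <- list(TO = 0.60, HMax = 0.85, HS = 1.00, period = 1.0)
  p <- predict_assist_times(prev)
  expect_equal(p$t_start, 1.60)
  expect_equal(p$t_peak, 1.85)
  expect_equal(p$t_end, 2.00)
  expect_equal(p$Ta, 0.40)
  expect_error(predict_assist_times(list(TO = 0.9, HMax = 0.85, HS = 1,
                                         period = 1)), "TO < HMax < HS")
  expect_error(predict_assist_times(list(TO = 0.6, HMax = 0.85, HS = 1,
                                         period = -1)), "period")
})

test_that("prediction error under cadence jitter is bounded by the drift", {
  set.seed(12)
  periods <- 1 + runif(30, -0.05, 0.05)  # +/- 5% per-cycle jitter
  starts <- c(0, cumsum(periods))
  ev <- data.frame(TO = starts[1:30] + 0.6 * periods,
                   HMax = starts[1:30] + 0.85 * periods,
                   HS = starts[1:30] + 1.0 * periods)
  errs <- c(); drifts <- c()
  for (k in 1:29) {
    p <- predict_assist_times(list(TO = ev$TO[k], HMax = ev$HMax[k],
                                   HS = ev$HS[k], period = periods[k]))
    errs <- c(errs, abs(c(p$t_start - ev$TO[k + 1],
                          p$t_peak - ev$HMax[k + 1],
                          p$t_end - ev$HS[k + 1])))
    drifts <- c(drifts, abs(periods[k + 1] - periods[k]))
  }
  expect_lte(median(errs), median(drifts) * 2)
  expect_lt(median(errs), 0.1)  # well under a tenth of a second
})

test_that("planning emits one profile per completed swing, anchored", {
  # ten complete swings per leg
  l <- lapply(0:9, function(k) c(TO = 0.6 + k, HMax = 0.85 + k, HS = 1 + k))
  r <- lapply(0:9, function(k) c(TO = 0.1 + k, HMax = 0.35 + k, HS = 0.5 + k))
  mk <- function(side, evs) timeline_of(
    paste0(side, "-", rep(c("TO", "HMax", "HS"), length(evs))),
    round(unlist(evs) * 200))
  tl <- rbind(mk("L", l), mk("R", r))
  tl <- tl[order(tl$sample_index), ]
  class(tl) <- c("event_timeline", "data.frame")
  states <- rep("LW", 2200)
  pl <- plan_assistance(states, tl, A = 40, f = 2)
  expect_identical(nrow(pl), 20L)
  expect_identical(sum(pl$leg == "L"), 10L)
  expect_identical(sum(pl$leg == "R"), 10L)
  expect_true(all(pl$A_N == 40 & pl$f_N == 2))
  # anchoring: window start/end exactly at the swing's TO and HS
  lrows <- pl[pl$leg == "L", ]
  expect_equal(lrows$t_start_s, 0.6 + 0:9, tolerance = 1e-9)
  expect_equal(lrows$t_end_s, 1.0 + 0:9, tolerance = 1e-9)
  expect_equal(lrows$t_peak_s, 0.85 + 0:9, tolerance = 1e-3 * 0.4)
  # standing bout: all profiles zero-force
  pl_sd <- plan_assistance(rep("SD", 2200), tl)
  expect_identical(nrow(pl_sd), 20L)
  expect_true(all(pl_sd$A_N == 0 & pl_sd$f_N == 0))
  # empty timeline: empty plan
  expect_identical(nrow(plan_assistance(states, timeline_of(character(0),
                                                            integer(0)))),
                   0L)
})

test_that("state gating matches a brute-force per-swing majority recount", {
  spec <- gait_cycle_spec(seed = 31)
  sim <- generate_cycle(spec, 12)
  tl <- sim$timeline
  n <- nrow(sim$stream)
  set.seed(31)
  # alternate LW / US in 400-sample blocks
  states <- rep(rep(c("LW", "US"), length.out = ceiling(n / 400)),
                each = 400)[1:n]
  pl <- plan_assistance(states, tl, A = 40, f = 2)
  sw <- rbind(cbind(gaitrec:::leg_swings(tl, "L", 200), leg = "L"),
              cbind(gaitrec:::leg_swings(tl, "R", 200), leg = "R"))
  expect_identical(nrow(pl), nrow(sw))
  recount <- vapply(seq_len(nrow(sw)), function(k) {
    seg <- states[(sw$to_idx[k] + 1):(sw$hs_idx[k] + 1)]
    tb <- sort(table(seg), decreasing = TRUE)
    names(tb)[1] == "LW"
  }, logical(1))
  pl_ord <- pl[order(pl$leg, pl$t_start_s), ]
  sw_ord <- order(sw$leg, sw$TO)
  expect_identical(unname(pl_ord$A_N > 0), unname(recount[sw_ord]))
})

test_that("sampled trajectories and plan CSVs are well-formed", {
  p <- assist_profile(A = 40, Ta = 0.4, alpha = -0.5, f = 2, t_start = 1.6)
  tr <- sample_profile(p, 200)
  expect_equal(tr$time_s[1], 1.6)
  expect_true(all(tr$force_N >= 0))
  pl <- plan_assistance(rep("LW", 500), perfect_timeline(2), A = 40, f = 2)
  f <- tempfile(fileext = ".csv")
  write_plan(pl, f)
  back <- read.csv(f)
  expect_identical(nrow(back), nrow(pl))
  expect_identical(names(back), names(pl))
})
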