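test_that("falling zero crossings of a sine land at its analytic zeros", {
  t <- (0:399) / 200
  expect_identical(detect_hs(sin(2 * pi * t), min_separation = 50),
                   c(100L, 300L))
  expect_identical(detect_hs(rep(1, 100)), integer(0))
  expect_identical(detect_hs(rep(0, 100)), integer(0))
  expect_identical(detect_hs(numeric(1)), integer(0))
})

test_that("detect_hs equals a brute-force scan over adjacent pairs", {
  set.seed(42)
  for (rep_ in 1:20) {
    x <- cumsum(rnorm(300))
    brute <- integer(0)
    for (k in seq_len(length(x) - 1))
      if (x[k] > 1e-9 && x[k + 1] <= 1e-9) brute <- c(brute, k)
    expect_identical(detect_hs(x), brute)
  }
})

test_that("detections are shift-equivariant and amplitude-invariant", {
  set.seed(7)
  x <- sin(2 * pi * (0:999) / 100) + rnorm(1000, sd = 0.05)
  for (k in c(13, 57)) {
    shifted <- x[(k + 1):length(x)]
    base <- detect_hs(x)
    expect_identical(detect_hs(shifted), base[base > k] - as.integer(k))
  }
  expect_identical(detect_hs(3.7 * x), detect_hs(x))
  expect_identical(detect_to(2.5 * x, min_separation = 50,
                             min_prominence = 2.5 * 0.5),
                   detect_to(x, min_separation = 50, min_prominence = 0.5))
})

test_that("trough detection finds the analytic minima of a cosine", {
  t <- (0:400) / 200
  x <- -cos(2 * pi * t)
  got <- detect_to(x, min_separation = 100, min_prominence = 0.5)
  expect_identical(got, 200L)  # interior trough at t = 1 s
  expect_identical(detect_to(rep(0, 100)), integer(0))
  expect_identical(detect_to(numeric(2)), integer(0))
})

test_that("timeline assembly keeps a perfect cycle and drops duplicates", {
  tl <- perfect_timeline(1)
  per <- split(tl$sample_index, phase_of(tl$side, tl$event))
  bt <- build_timeline(per)
  expect_identical(bt$n_dropped, 0L)
  expect_identical(bt$timeline$sample_index, tl$sample_index)
  # inject a duplicate L-HS mid-cycle
  per2 <- per
  per2[["L-HS"]] <- sort(c(per2[["L-HS"]], 90L))
  bt2 <- build_timeline(per2)
  expect_identical(bt2$n_dropped, 1L)
  expect_identical(bt2$dropped$sample_index, 90L)
  expect_identical(bt2$timeline$sample_index, tl$sample_index)
})

test_that("timeline retention matches the exhaustive subsequence oracle", {
  set.seed(11)
  cls <- phase_classes()
  for (rep_ in 1:25) {
    n <- sample(4:11, 1)
    idx <- sort(sample.int(100, n))
    code <- sample.int(6, n, replace = TRUE)
    per <- split(idx, cls[code])
    for (p in setdiff(cls, names(per))) per[[p]] <- integer(0)
    kept <- suppressWarnings(nrow(build_timeline(per)$timeline))
    expect_identical(kept, oracle_longest_valid(idx, code))
  }
})

test_that("order validation reports violations like an independent walk", {
  tl <- perfect_timeline(3)
  expect_identical(nrow(validate_event_order(tl)), 0L)
  # swap R-TO and R-HMax in the second cycle: exactly one violation
  swapped <- tl
  swapped[c(8, 9), c("side", "event")] <- swapped[c(9, 8), c("side", "event")]
  expect_identical(nrow(validate_event_order(swapped)), 1L)
  # a duplicated event is cyclically behind the expectation: one violation
  dup <- rbind(tl, tl[7, ])
  dup$sample_index[nrow(dup)] <- 210L
  dup <- dup[order(dup$sample_index), ]
  expect_identical(nrow(validate_event_order(dup)), 1L)
  # independent reimplementation of the walk, compared on random shuffles
  naive_count <- function(tl) {
    cls <- phase_classes()
    ph <- phase_of(tl$side, tl$event)
    pos <- match(ph, cls)
    expect_ <- NULL; last <- -Inf; bad <- 0L
    for (i in seq_along(ph)) {
      ahead <- if (is.null(expect_)) 0 else (pos[i] - match(expect_, cls)) %% 6
      if (ahead <= 3 && tl$sample_index[i] > last) {
        expect_ <- cls[(pos[i] %% 6) + 1]
        last <- tl$sample_index[i]
      } else bad <- bad + 1L
    }
    bad
  }
  set.seed(3)
  for (rep_ in 1:20) {
    sh <- tl[sample.int(nrow(tl)), ]
    sh <- sh[order(sh$sample_index), ]
    sh$sample_index <- sort(sample.int(500, nrow(sh)))
    expect_identical(nrow(validate_event_order(sh)), naive_count(sh))
  }
})

test_that("phase labeling assigns each sample the preceding event's class", {
  tl <- timeline_of(c("L-HS", "R-TO"), c(0L, 10L))
  lab <- label_phases(tl, 20)
  expect_identical(lab, c(rep("L-HS", 10), rep("R-TO", 10)))
  expect_identical(label_phases(timeline_of("L-TO", 0L), 5),
                   rep("L-TO", 5))
  # before the first event: the cyclically preceding class
  lab2 <- label_phases(timeline_of("R-TO", 4L), 8)
  expect_identical(lab2, c(rep("L-HS", 4), rep("R-TO", 4)))
  expect_error(label_phases(empty <- timeline_of(character(0), integer(0)),
                            5), "empty")
  expect_error(label_phases(tl, 10), "exceed")
})

test_that("phase labels partition the stream and match event gaps", {
  tl <- perfect_timeline(5)
  n <- 1000
  lab <- label_phases(tl, n)
  expect_length(lab, n)
  expect_true(all(lab %in% phase_classes()))
  # label changes only at event indices
  changes <- which(lab[-1] != lab[-n])  # 0-based index of change = value
  expect_true(all(changes %in% tl$sample_index))
  # class counts equal the summed inter-event gaps
  gaps <- diff(c(tl$sample_index, n))
  ph <- phase_of(tl$side, tl$event)
  for (p in phase_classes())
    expect_identical(sum(lab == p), as.integer(sum(gaps[ph == p])))
})

test_that("noisy synthetic bouts are labeled nearly perfectly end to end", {
  spec <- gait_cycle_spec(seed = 21)
  sim <- generate_cycle(spec, 20)
  res <- label_stream(sim$stream)
  expect_identical(nrow(validate_event_order(res$timeline)), 0L)
  expect_gte(recovery_rate(sim$timeline, res$timeline), 0.99)
  truth_lab <- label_phases(sim$timeline, nrow(sim$stream))
  expect_gt(mean(res$labels == truth_lab), 0.97)
})

test_that("stream and timeline CSVs round-trip", {
  spec <- gait_cycle_spec(seed = 4)
  sim <- generate_cycle(spec, 2)
  fs <- tempfile(fileext = ".csv"); ft <- tempfile(fileext = ".csv")
  write_imu_stream(sim$stream, fs)
  write_event_timeline(sim$timeline, ft)
  s2 <- read_imu_stream(fs)
  expect_equal(as.data.frame(s2), as.data.frame(sim$stream),
               tolerance = 1e-12)
  t2 <- read_event_timeline(ft)
  expect_identical(t2$sample_index, sim$timeline$sample_index)
  expect_identical(t2$event, sim$timeline$event)
})
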