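#' Validate and default a pipeline configuration
#'
#' Fills the full-scale defaults (penalty `C = 2`, `gamma = "scale"`,
#' sequence length `n = 5`, LSTM hidden 128 / FC 32, 200 epochs, batch 64,
#' 200 Hz) and validates every supplied field, reporting all violations at
#' once; unknown keys are rejected with the nearest valid key suggested.
#'
#' @param raw Named list of overrides (possibly empty).
#' @return A `pipeline_config` list.
#' @export
validate_config <- function(raw = list()) {
  defaults <- list(
    sample_rate = 200, n = 5L, svm_C = 2, svm_gamma = "scale",
    hidden = 128L, fc = 32L, epochs = 200L, batch = 64L, lr = 1e-3,
    seed = 1L, states = motion_states(), n_subjects = 5L,
    n_train_subjects = NULL, cycles_per_state = 10L,
    planner_A = 40, planner_f = 2, planner_form = "product",
    svm_stride = 1L, noise_sigma_gyro = 0.05, noise_sigma_acc = 0.10
  )
  errs <- character(0)
  unknown <- setdiff(names(raw), names(defaults))
  for (key in unknown) {
    near <- names(defaults)[which.min(utils::adist(key, names(defaults)))]
    errs <- c(errs, sprintf("unknown key '%s' (did you mean '%s'?)",
                            key, near))
  }
  cfg <- utils::modifyList(defaults, raw[setdiff(names(raw), unknown)])
  if (is.null(cfg$n_train_subjects))
    cfg$n_train_subjects <- max(1L, cfg$n_subjects - 1L)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$epochs >= 1, "epochs must be >= 1")
  chk(cfg$batch >= 1, "batch must be >= 1")
  chk(cfg$n >= 1, "n (sequence length) must be >= 1")
  chk(cfg$hidden >= 1, "hidden must be >= 1")
  chk(cfg$svm_C > 0, "svm_C must be positive")
  chk(cfg$sample_rate > 0, "sample_rate must be positive")
  chk(cfg$lr > 0, "lr must be positive")
  chk(all(cfg$states %in% motion_states()),
      paste("states must be a subset of",
            paste(motion_states(), collapse = ", ")))
  chk(cfg$n_subjects >= 2, "n_subjects must be >= 2 (train and test)")
  chk(is.null(cfg$n_train_subjects) ||
        cfg$n_train_subjects < cfg$n_subjects,
      "n_train_subjects must be smaller than n_subjects")
  chk(cfg$planner_form %in% c("product", "simple"),
      "planner_form must be 'product' or 'simple'")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "pipeline_config")
}

# ---- model-level convenience wrappers ------------------------------------

#' Train the motion-state recognizer on a labeled dataset
#'
#' Fits channel statistics on the training streams, standardizes, stacks
#' per-sample 30-channel feature vectors (optionally thinned by `stride` —
#' consecutive 200 Hz samples are highly redundant) and fits the
#' binary-tree SVM.
#'
#' @param dataset Training `labeled_dataset`.
#' @param C,gamma SVM hyperparameters.
#' @param stride Keep every `stride`-th sample for training.
#' @param max_node_samples Per-node training cap, see [fit_tree()].
#' @return A `state_model`: list with `tree`, `stats`, `classes`.
#' @export
train_state_model <- function(dataset, C = 2, gamma = "scale", stride = 1L,
                              max_node_samples = Inf) {
  stats <- fit_stats(dataset$streams)
  ch <- gait_channels()
  Xs <- lapply(seq_along(dataset$streams), function(i) {
    m <- as.matrix(standardize(dataset$streams[[i]], stats)[, ch])
    m[seq(1, nrow(m), by = stride), , drop = FALSE]
  })
  y <- unlist(lapply(seq_along(dataset$streams), function(i) {
    lab <- dataset$labels[[i]]
    lab[seq(1, length(lab), by = stride)]
  }))
  X <- do.call(rbind, Xs)
  classes <- motion_states()[motion_states() %in% unique(y)]
  tree <- fit_tree(build_tree(classes), X, y, C = C, gamma = gamma,
                   max_node_samples = max_node_samples)
  structure(list(tree = tree, stats = stats, classes = classes),
            class = "state_model")
}

#' Predict per-sample motion states for a dataset
#'
#' @param model A `state_model`.
#' @param dataset A `labeled_dataset`.
#' @param stride Evaluate every `stride`-th sample.
#' @return List with `y_true` and `y_pred` across all streams.
#' @export
predict_state_dataset <- function(model, dataset, stride = 1L) {
  ch <- gait_channels()
  y_true <- character(0); y_pred <- character(0)
  for (i in seq_along(dataset$streams)) {
    m <- as.matrix(standardize(dataset$streams[[i]], model$stats)[, ch])
    keep <- seq(1, nrow(m), by = stride)
    y_pred <- c(y_pred, predict_state(model$tree, m[keep, , drop = FALSE]))
    y_true <- c(y_true, dataset$labels[[i]][keep])
  }
  list(y_true = y_true, y_pred = y_pred)
}

#' Build a phase sequence set from level-walking streams
#'
#' Standardizes each LW stream with the supplied statistics, labels its
#' samples from the ground-truth (or detected) event timeline and cuts
#' sliding windows.
#'
#' @param dataset A `labeled_dataset` containing LW streams.
#' @param stats `channel_stats` (fitted on training streams).
#' @param n Sequence length.
#' @param stride Window stride.
#' @return A `sequence_set` pooling all LW streams.
#' @export
phase_sequences <- function(dataset, stats, n = 5L, stride = 1L) {
  idx <- which(dataset$state == "LW")
  if (!length(idx)) stop("dataset contains no LW streams")
  xs <- list(); ys <- list()
  for (i in idx) {
    s <- standardize(dataset$streams[[i]], stats)
    labs <- label_phases(dataset$event_truth[[i]],
                         nrow(dataset$streams[[i]]))
    sq <- make_sequences(s, labs, n = n, stride = stride)
    xs[[length(xs) + 1L]] <- sq$x
    ys[[length(ys) + 1L]] <- sq$y
  }
  x <- do.call(abind_first, xs)
  structure(list(x = x, y = unlist(ys), n = n), class = "sequence_set")
}

# bind arrays along the first dimension
abind_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  total <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, c(total, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    n <- dim(a)[1]
    if (n) out[at + seq_len(n), , ] <- a
    at <- at + n
  }
  out
}

#' Run the full pipeline: simulate, label, train, evaluate, plan
#'
#' Generates a multi-subject synthetic dataset, splits it subject-wise,
#' trains the state recognizer (binary-tree SVM) and the phase recognizer
#' (LSTM), evaluates both on the held-out subjects, and plans state-gated
#' assistance for the held-out level-walking bouts using detected events
#' and predicted states. All artifacts are written under `out_dir`.
#'
#' @param config A `pipeline_config` (or raw list passed through
#'   [validate_config()]).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage messages.
#' @return List with `state_report`, `phase_report`, `plan` and `paths`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("gaitrec_"),
                         quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stopwatch <- function() proc.time()[["elapsed"]]
  t0 <- stopwatch()

  say("simulate: %d subjects x %d states x %d cycles (seed %d)",
      config$n_subjects, length(config$states), config$cycles_per_state,
      config$seed)
  spec <- gait_cycle_spec(noise_sigma_gyro = config$noise_sigma_gyro,
                          noise_sigma_acc = config$noise_sigma_acc,
                          sample_rate = config$sample_rate)
  ds <- generate_dataset(config$states, config$n_subjects,
                         config$cycles_per_state, seed = config$seed,
                         spec = spec)
  sp <- subject_split(ds, config$n_train_subjects)

  say("train-state: binary-tree SVM (C=%g, gamma=%s) [%.1fs]",
      config$svm_C, as.character(config$svm_gamma), stopwatch() - t0)
  state_model <- train_state_model(sp$train, C = config$svm_C,
                                   gamma = config$svm_gamma,
                                   stride = config$svm_stride,
                                   max_node_samples = 4000L)
  pr <- predict_state_dataset(state_model, sp$test,
                              stride = config$svm_stride)
  state_report <- evaluate_predictions(pr$y_true, pr$y_pred,
                                       state_model$classes)

  say("train-phase: LSTM (hidden=%d, epochs=%d, batch=%d) [%.1fs]",
      config$hidden, config$epochs, config$batch, stopwatch() - t0)
  if (!"LW" %in% config$states)
    stop("phase recognition requires LW among the configured states")
  train_seq <- phase_sequences(sp$train, state_model$stats, n = config$n)
  phase_model <- train_lstm(train_seq, hidden = config$hidden,
                            fc = config$fc, epochs = config$epochs,
                            batch = config$batch, lr = config$lr,
                            seed = config$seed)
  test_seq <- phase_sequences(sp$test, state_model$stats, n = config$n)
  phase_report <- evaluate_predictions(test_seq$y,
                                       predict_phase(phase_model, test_seq),
                                       phase_classes())

  say("plan: event detection + state-gated assistance [%.1fs]",
      stopwatch() - t0)
  plans <- list()
  test_lw <- which(sp$test$state == "LW")
  for (i in test_lw) {
    stream <- sp$test$streams[[i]]
    lab <- label_stream(stream, nominal_period = spec$cycle_period,
                        with_labels = FALSE)
    m <- as.matrix(standardize(stream, state_model$stats)[, gait_channels()])
    states <- predict_state(state_model$tree, m)
    plans[[length(plans) + 1L]] <-
      plan_assistance(states, lab$timeline, A = config$planner_A,
                      f = config$planner_f,
                      sample_rate = config$sample_rate,
                      form = config$planner_form)
  }
  plan <- if (length(plans)) do.call(rbind, plans) else empty_plan()

  paths <- list(
    state_model = file.path(out_dir, "state_model.json"),
    phase_model = file.path(out_dir, "phase_model.json"),
    state_report = file.path(out_dir, "state_report.json"),
    phase_report = file.path(out_dir, "phase_report.json"),
    plan = file.path(out_dir, "plan.csv"),
    config = file.path(out_dir, "config.json")
  )
  write_state_model(state_model$tree, state_model$stats, paths$state_model)
  write_phase_model(phase_model, paths$phase_model)
  write_report(state_report, paths$state_report)
  write_report(phase_report, paths$phase_report)
  write_plan(plan, paths$plan)
  cfg_out <- unclass(config)
  jsonlite::write_json(cfg_out, paths$config, auto_unbox = TRUE, digits = NA)
  say("done: state acc %.4f, phase acc %.4f [%.1fs]",
      state_report$accuracy, phase_report$accuracy, stopwatch() - t0)
  list(state_report = state_report, phase_report = phase_report,
       plan = plan, paths = paths, state_model = state_model,
       phase_model = phase_model)
}
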