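#' Confusion matrix with column normalization
#'
#' Rows index the predicted class and columns the true class. The
#' column-normalized matrix divides each column by its true-class support,
#' so every supported column sums to 1; zero-support columns are all-zero
#' and flagged.
#'
#' @param y_true,y_pred Label vectors of equal length; labels must belong
#'   to `classes`.
#' @param classes Class levels fixing the matrix order.
#' @return List with `counts`, `normalized` (both `K x K`,
#'   predicted x true) and `zero_support` (logical per class).
#' @export
confusion <- function(y_true, y_pred, classes) {
  stopifnot(length(y_true) == length(y_pred))
  unknown <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  counts <- table(factor(y_pred, levels = classes),
                  factor(y_true, levels = classes))
  counts <- unclass(counts)
  dimnames(counts) <- list(pred = classes, true = classes)
  support <- colSums(counts)
  norm <- sweep(counts, 2, pmax(support, 1), "/")
  norm[, support == 0] <- 0
  list(counts = counts, normalized = norm, zero_support = support == 0)
}

#' Classification metrics from confusion counts
#'
#' Accuracy is `trace / total`. Macro-F1 is the unweighted mean of
#' per-class F1 scores, excluding (and flagging) classes with no true and
#' no predicted instances. MCC is the multiclass covariance-form
#' generalization of the Matthews correlation coefficient,
#' `(c*s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2))(s^2 - sum(t_k^2)))`
#' with `c` the correct count, `s` the total, and `p_k`, `t_k` the
#' predicted/true class totals; a vanishing denominator yields 0.
#'
#' @param counts Square confusion-count matrix (predicted x true).
#' @return List with `accuracy`, `macro_f1`, `mcc`, `per_class_f1` and
#'   `f1_excluded` (classes without support on either axis).
#' @export
metrics <- function(counts) {
  counts <- as.matrix(counts)
  s <- sum(counts)
  if (s == 0) stop("confusion counts are empty")
  tp <- diag(counts)
  p_k <- rowSums(counts)  # predicted totals
  t_k <- colSums(counts)  # true totals
  acc <- sum(tp) / s
  denom <- p_k + t_k
  f1 <- ifelse(denom > 0, 2 * tp / denom, NA_real_)
  excluded <- denom == 0
  macro_f1 <- mean(f1[!excluded])
  num <- sum(tp) * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  mcc <- if (den == 0) 0 else num / den
  list(accuracy = acc, macro_f1 = macro_f1, mcc = mcc,
       per_class_f1 = f1, f1_excluded = excluded)
}

#' Evaluate predictions into a report
#'
#' @param y_true,y_pred Label vectors.
#' @param classes Class levels.
#' @return An `eval_report`: metrics plus count and column-normalized
#'   confusion matrices.
#' @export
evaluate_predictions <- function(y_true, y_pred, classes) {
  cm <- confusion(y_true, y_pred, classes)
  m <- metrics(cm$counts)
  structure(c(m, cm), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  macro-F1 %.4f  MCC %.4f\n",
              x$accuracy, x$macro_f1, x$mcc))
  invisible(x)
}

#' Subject-wise train/test split
#'
#' Whole subjects are assigned to one side only, deterministically by
#' subject-id order: the first `n_train_subjects` train, the rest test
#' (matching the 20/5 and 22/3 hold-out protocols).
#'
#' @param dataset A `labeled_dataset`.
#' @param n_train_subjects Number of training subjects (must leave at
#'   least one test subject).
#' @return List with `train` and `test` `labeled_dataset`s.
#' @export
subject_split <- function(dataset, n_train_subjects) {
  ids <- sort(unique(dataset$subject))
  if (n_train_subjects >= length(ids))
    stop("n_train_subjects must leave at least one test subject")
  train_ids <- ids[seq_len(n_train_subjects)]
  list(train = dataset_subset(dataset, dataset$subject %in% train_ids),
       test = dataset_subset(dataset, !dataset$subject %in% train_ids))
}

dataset_subset <- function(dataset, keep) {
  structure(list(streams = dataset$streams[keep],
                 state = dataset$state[keep],
                 subject = dataset$subject[keep],
                 labels = dataset$labels[keep],
                 event_truth = dataset$event_truth[keep]),
            class = "labeled_dataset")
}

#' Subject-grouped k-fold cross-validation
#'
#' Subjects are shuffled once with the given seed and dealt into `k` folds;
#' no subject spans folds. For each fold the supplied trainer is fitted on
#' the remaining subjects and evaluated on the fold.
#'
#' @param dataset A `labeled_dataset`.
#' @param k Number of folds (default 5).
#' @param trainer `function(train_dataset)` returning a fitted object.
#' @param predictor `function(fit, test_dataset)` returning
#'   `list(y_true =, y_pred =)`.
#' @param classes Class levels for the confusion matrices.
#' @param seed Integer seed for the fold shuffle.
#' @return An `eval_report` with pooled confusion counts, per-fold reports
#'   in `folds`, and `fold_mean` / `fold_sd` of each metric.
#' @export
kfold_cv <- function(dataset, k = 5, trainer, predictor, classes,
                     seed = 1L) {
  ids <- sort(unique(dataset$subject))
  if (k < 2) stop("k must be >= 2")
  if (length(ids) < k) stop("fewer subjects than folds")
  fold_of <- with_local_seed(seed, {
    stats::setNames(rep(seq_len(k), length.out = length(ids))[
      order(sample.int(length(ids)))], ids)
  })
  folds <- list()
  pooled_true <- character(0); pooled_pred <- character(0)
  for (fold in seq_len(k)) {
    test_ids <- ids[fold_of == fold]
    fit <- trainer(dataset_subset(dataset, !dataset$subject %in% test_ids))
    pr <- predictor(fit, dataset_subset(dataset,
                                        dataset$subject %in% test_ids))
    folds[[fold]] <- evaluate_predictions(pr$y_true, pr$y_pred, classes)
    pooled_true <- c(pooled_true, pr$y_true)
    pooled_pred <- c(pooled_pred, pr$y_pred)
  }
  rep_ <- evaluate_predictions(pooled_true, pooled_pred, classes)
  per <- sapply(folds, function(f) c(accuracy = f$accuracy,
                                     macro_f1 = f$macro_f1, mcc = f$mcc))
  rep_$folds <- folds
  rep_$fold_mean <- rowMeans(per)
  rep_$fold_sd <- apply(per, 1, stats::sd)
  rep_$fold_assignment <- fold_of
  rep_
}

#' Write an evaluation report to JSON (+ CSV confusion matrix)
#'
#' @param report An `eval_report`.
#' @param path JSON output path; the count and normalized confusion
#'   matrices are written alongside as CSVs.
#' @export
write_report <- function(report, path) {
  out <- list(accuracy = report$accuracy, macro_f1 = report$macro_f1,
              mcc = report$mcc)
  if (!is.null(report$fold_mean)) {
    out$fold_mean <- as.list(report$fold_mean)
    out$fold_sd <- as.list(report$fold_sd)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  base <- sub("\\.json$", "", path)
  utils::write.csv(as.data.frame(report$counts),
                   paste0(base, "_confusion_counts.csv"), row.names = TRUE)
  utils::write.csv(as.data.frame(round(report$normalized, 4)),
                   paste0(base, "_confusion_normalized.csv"),
                   row.names = TRUE)
  invisible(path)
}
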