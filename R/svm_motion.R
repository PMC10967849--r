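#' Radial basis function kernel
#'
#' `K(a, b) = exp(-gamma * ||a - b||^2)`; symmetric, and `K(a, a) = 1`.
#'
#' @param A,B Numeric matrices (rows = samples).
#' @param gamma Kernel width.
#' @return `nrow(A)` x `nrow(B)` kernel matrix.
#' @export
rbf_kernel <- function(A, B, gamma) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Resolve the "scale" kernel width
#'
#' `gamma = 1 / (n_features * var(all training feature values))`, the
#' data-driven width used throughout the motion-state recognizer.
#'
#' @param X Training feature matrix.
#' @return Numeric gamma.
#' @export
resolve_gamma <- function(X) {
  1 / (ncol(X) * stats::var(as.vector(as.matrix(X))))
}

#' Train a soft-margin binary RBF-SVM
#'
#' Solves the C-SVM quadratic program (via the SMO solver in \pkg{e1071})
#' and stores the support vectors, the dual coefficients
#' `lambda_i * y_i` (bounded in `[-C, C]` by the box constraint) and the
#' bias, so the decision function is the explicit kernel expansion
#' `f(x) = sum_i lambda_i y_i K(x_i, x) + b` evaluated by
#' [svm_decision_values()].
#'
#' @param X Numeric feature matrix (standardized).
#' @param y Labels in `{-1, +1}`.
#' @param C Penalty factor (default 2).
#' @param gamma Kernel width, or `"scale"` to resolve via
#'   [resolve_gamma()].
#' @param tolerance Termination tolerance of the quadratic-program solver.
#' @return An `svm_binary` model.
#' @export
train_binary <- function(X, y, C = 2, gamma = "scale", tolerance = 0.001) {
  X <- as.matrix(X)
  if (!all(y %in% c(-1, 1))) stop("y must be coded -1 / +1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (identical(gamma, "scale")) gamma <- resolve_gamma(X)
  yf <- factor(y, levels = c(1, -1))
  fit <- e1071::svm(x = X, y = yf, type = "C-classification",
                    kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE, tolerance = tolerance)
  # libsvm orients the decision toward the class appearing first in the
  # data; normalize so f(x) > 0 always predicts the +1 class
  flip <- if (fit$levels[fit$labels[1]] == "1") 1 else -1
  structure(list(sv = unname(fit$SV),
                 coefs = flip * as.numeric(fit$coefs),
                 b = -flip * fit$rho, gamma = gamma, C = C),
            class = "svm_binary")
}

#' Kernel-expansion decision values
#'
#' @param model An `svm_binary`.
#' @param X Matrix of probe points (rows).
#' @return Numeric vector `f(x) = sum_i lambda_i y_i K(x_i, x) + b`;
#'   `sign(f) = +1` predicts the `+1` class.
#' @export
svm_decision_values <- function(model, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  as.numeric(rbf_kernel(X, model$sv, model$gamma) %*% model$coefs + model$b)
}

# ---- binary-tree multiclass composition ----------------------------------

#' Build a balanced binary-tree skeleton over a class list
#'
#' Internal nodes split the class list in half (left gets the first
#' `ceiling(k/2)` classes in the given order, recursively); leaves hold
#' single classes. With the default ten motion states this yields nine
#' internal nodes and depth four. The ordering is deterministic and
#' configurable via the order of `classes`.
#'
#' @param classes Character vector of class names (>= 2, unique).
#' @return A tree skeleton (nested list).
#' @export
build_tree <- function(classes) {
  if (length(classes) < 2) stop("need at least 2 classes")
  if (anyDuplicated(classes)) stop("classes must be unique")
  split_node <- function(cls) {
    if (length(cls) == 1L) return(list(type = "leaf", class = cls))
    k <- ceiling(length(cls) / 2)
    list(type = "node",
         left_classes = cls[seq_len(k)],
         right_classes = cls[-seq_len(k)],
         model = NULL,
         left = split_node(cls[seq_len(k)]),
         right = split_node(cls[-seq_len(k)]))
  }
  structure(split_node(classes), class = "svm_tree")
}

tree_leaves <- function(node) {
  if (node$type == "leaf") return(node$class)
  c(tree_leaves(node$left), tree_leaves(node$right))
}

tree_depth <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

tree_n_internal <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + tree_n_internal(node$left) + tree_n_internal(node$right)
}

#' Fit every internal node of a tree skeleton
#'
#' Each internal node is trained on the samples belonging to its class
#' subset, labeled `+1` for the left branch and `-1` for the right branch.
#' `gamma = "scale"` is resolved once on the full training matrix so all
#' nodes share one kernel width.
#'
#' @param skeleton From [build_tree()]; its leaves must match the classes
#'   present in `y`.
#' @param X Standardized feature matrix.
#' @param y Class labels.
#' @param C Penalty factor (default 2).
#' @param gamma `"scale"` or numeric.
#' @param max_node_samples Cap on per-node training samples; larger sets
#'   are thinned evenly (deterministic). `Inf` disables.
#' @return A fitted `svm_tree`.
#' @export
fit_tree <- function(skeleton, X, y, C = 2, gamma = "scale",
                     max_node_samples = Inf) {
  X <- as.matrix(X)
  leaves <- tree_leaves(skeleton)
  if (!setequal(leaves, unique(y)))
    stop("classes in y must match the tree leaves")
  if (identical(gamma, "scale")) gamma <- resolve_gamma(X)
  fit_node <- function(node) {
    if (node$type == "leaf") return(node)
    inL <- y %in% node$left_classes
    inR <- y %in% node$right_classes
    if (!any(inL))
      stop("no training samples for branch classes ",
           paste(node$left_classes, collapse = ","))
    if (!any(inR))
      stop("no training samples for branch classes ",
           paste(node$right_classes, collapse = ","))
    sel <- which(inL | inR)
    if (length(sel) > max_node_samples)
      sel <- sel[round(seq(1, length(sel), length.out = max_node_samples))]
    node$model <- train_binary(X[sel, , drop = FALSE],
                               ifelse(y[sel] %in% node$left_classes, 1, -1),
                               C = C, gamma = gamma)
    node$left <- fit_node(node$left)
    node$right <- fit_node(node$right)
    node
  }
  structure(fit_node(skeleton), class = "svm_tree")
}

#' Predict motion states by root-to-leaf descent
#'
#' At each internal node the kernel-expansion decision value routes the
#' sample: `f >= 0` takes the first (left) branch — a decision value of
#' exactly zero deterministically follows the first branch. With
#' `audit = TRUE` (single sample) the per-node decision values along the
#' path are returned.
#'
#' @param tree A fitted `svm_tree`.
#' @param X Feature matrix (rows = samples) or a single feature vector.
#' @param audit Return the per-node decision path (single sample only).
#' @return Character vector of predicted states, or (audit) a list with
#'   `state` and `decisions`.
#' @export
predict_state <- function(tree, X, audit = FALSE) {
  if (tree$type == "node" && is.null(tree$model))
    stop("tree is not fitted; call fit_tree() first")
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  if (audit) {
    stopifnot(nrow(X) == 1)
    path <- c()
    node <- tree
    while (node$type == "node") {
      f <- svm_decision_values(node$model, X)
      nm <- paste(paste(node$left_classes, collapse = "+"), "vs",
                  paste(node$right_classes, collapse = "+"))
      path <- c(path, stats::setNames(f, nm))
      node <- if (f >= 0) node$left else node$right
    }
    return(list(state = node$class, decisions = path))
  }
  out <- character(nrow(X))
  descend <- function(node, rows) {
    if (!length(rows)) return()
    if (node$type == "leaf") { out[rows] <<- node$class; return() }
    f <- svm_decision_values(node$model, X[rows, , drop = FALSE])
    descend(node$left, rows[f >= 0])
    descend(node$right, rows[f < 0])
  }
  descend(tree, seq_len(nrow(X)))
  out
}

#' @export
print.svm_tree <- function(x, ...) {
  cat("svm_tree:", length(tree_leaves(x)), "classes,",
      tree_n_internal(x), "internal nodes, depth", tree_depth(x),
      if (x$type == "node" && is.null(x$model)) "(skeleton)" else "(fitted)",
      "\n")
  invisible(x)
}

#' Serialize a fitted state-recognition model
#'
#' Writes a JSON manifest holding the tree structure, hyperparameters and
#' per-node support vectors / dual coefficients, plus the channel
#' statistics used for standardization.
#'
#' @param tree Fitted `svm_tree`.
#' @param stats `channel_stats` used at training time.
#' @param path Output `.json` path.
#' @return `read_state_model()` returns `list(tree, stats)`.
#' @export
write_state_model <- function(tree, stats, path) {
  ser <- function(node) {
    if (node$type == "leaf") return(list(type = "leaf", class = node$class))
    list(type = "node",
         left_classes = node$left_classes,
         right_classes = node$right_classes,
         model = list(sv = apply(node$model$sv, 1, as.list),
                      coefs = node$model$coefs, b = node$model$b,
                      gamma = node$model$gamma, C = node$model$C),
         left = ser(node$left), right = ser(node$right))
  }
  jsonlite::write_json(list(tree = ser(tree),
                            stats = lapply(unclass(stats), as.list)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_state_model
#' @export
read_state_model <- function(path) {
  raw <- jsonlite::read_json(path)
  de <- function(node) {
    if (node$type == "leaf")
      return(list(type = "leaf", class = node$class))
    sv <- do.call(rbind, lapply(node$model$sv, function(r) unlist(r)))
    list(type = "node",
         left_classes = unlist(node$left_classes),
         right_classes = unlist(node$right_classes),
         model = structure(list(sv = unname(sv),
                                coefs = unlist(node$model$coefs),
                                b = node$model$b, gamma = node$model$gamma,
                                C = node$model$C), class = "svm_binary"),
         left = de(node$left), right = de(node$right))
  }
  stats <- structure(list(mean = unlist(raw$stats$mean),
                          sd = unlist(raw$stats$sd),
                          constant = unlist(raw$stats$constant)),
                     class = "channel_stats")
  list(tree = structure(de(raw$tree), class = "svm_tree"), stats = stats)
}
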