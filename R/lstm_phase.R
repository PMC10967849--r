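#' LSTM gait-phase recognizer
#'
#' A from-scratch long short-term memory sequence classifier. Each cell
#' update follows the standard gate equations on the concatenation
#' `[h_{t-1}, x_t]`:
#' \deqn{f_t = \sigma(W_f [h_{t-1}, x_t] + b_f)}
#' \deqn{i_t = \sigma(W_i [h_{t-1}, x_t] + b_i)}
#' \deqn{o_t = \sigma(W_o [h_{t-1}, x_t] + b_o)}
#' \deqn{C_t = f_t \circ C_{t-1} + i_t \circ \tanh(W_c [h_{t-1}, x_t] + b_c)}
#' \deqn{h_t = o_t \circ \tanh(C_t)}
#' The final hidden state feeds a fully connected layer (rectifier) and a
#' softmax over the six gait phases. Training minimizes categorical
#' cross-entropy with Adam and backpropagation through time; gradients are
#' exact (verified against finite differences in the test suite).
#'
#' @name lstm_phase
NULL

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax <- function(A) {
  A <- A - apply(A, 1, max)
  E <- exp(A)
  E / rowSums(E)
}

add_bias <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize LSTM parameters
#'
#' Glorot-uniform weight initialization with a fixed seed; biases start at
#' zero. Defaults follow the full-scale recognizer (128 LSTM units, 32
#' fully connected units, 6 classes, 30 input channels); tests and desk-
#' scale runs use a smaller hidden size.
#'
#' @param input_size Channels per time step (default 30).
#' @param hidden LSTM units (default 128).
#' @param fc Fully connected units (default 32).
#' @param n_classes Output classes (default 6).
#' @param seed Integer seed for the initialization draw.
#' @return An `lstm_params` list of gate/head weight matrices and biases.
#' @export
lstm_init <- function(input_size = 30L, hidden = 128L, fc = 32L,
                      n_classes = 6L, seed = 1L) {
  with_local_seed(seed, {
    zin <- hidden + input_size
    structure(list(
      Wf = glorot(zin, hidden), bf = numeric(hidden),
      Wi = glorot(zin, hidden), bi = numeric(hidden),
      Wo = glorot(zin, hidden), bo = numeric(hidden),
      Wc = glorot(zin, hidden), bc = numeric(hidden),
      W1 = glorot(hidden, fc), b1 = numeric(fc),
      W2 = glorot(fc, n_classes), b2 = numeric(n_classes),
      hidden = hidden, input_size = input_size, fc = fc,
      n_classes = n_classes
    ), class = "lstm_params")
  })
}

#' One LSTM cell update
#'
#' @param params An `lstm_params`.
#' @param h_prev,C_prev Previous hidden and cell state: vectors of length
#'   `hidden`, or batch matrices (rows = samples).
#' @param x Input vector of length `input_size`, or batch matrix.
#' @return List with updated `h` and `C` (same shape as the inputs).
#' @export
cell_step <- function(params, h_prev, C_prev, x) {
  vec <- is.null(dim(h_prev))
  H <- if (vec) matrix(h_prev, 1) else h_prev
  Cp <- if (vec) matrix(C_prev, 1) else C_prev
  Xm <- if (is.null(dim(x))) matrix(x, 1) else x
  if (ncol(H) != params$hidden)
    stop("h_prev has length ", ncol(H), "; expected hidden size ",
         params$hidden)
  if (ncol(Xm) != params$input_size)
    stop("x has length ", ncol(Xm), "; expected input size ",
         params$input_size)
  Z <- cbind(H, Xm)
  f <- sigmoid(add_bias(Z %*% params$Wf, params$bf))
  i <- sigmoid(add_bias(Z %*% params$Wi, params$bi))
  o <- sigmoid(add_bias(Z %*% params$Wo, params$bo))
  g <- tanh(add_bias(Z %*% params$Wc, params$bc))
  Cn <- f * Cp + i * g
  h <- o * tanh(Cn)
  if (vec) list(h = as.numeric(h), C = as.numeric(Cn))
  else list(h = h, C = Cn)
}

# full forward pass over a batch of sequences; optionally keep the caches
# needed by backpropagation through time
lstm_forward_batch <- function(params, X, keep_cache = FALSE) {
  B <- dim(X)[1]; n <- dim(X)[2]
  H <- params$hidden
  h <- matrix(0, B, H); C <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", n)
  for (t in seq_len(n)) {
    xt <- X[, t, , drop = FALSE]
    dim(xt) <- c(B, dim(X)[3])
    Z <- cbind(h, xt)
    f <- sigmoid(add_bias(Z %*% params$Wf, params$bf))
    i <- sigmoid(add_bias(Z %*% params$Wi, params$bi))
    o <- sigmoid(add_bias(Z %*% params$Wo, params$bo))
    g <- tanh(add_bias(Z %*% params$Wc, params$bc))
    Cn <- f * C + i * g
    tc <- tanh(Cn)
    hn <- o * tc
    if (keep_cache)
      cache[[t]] <- list(Z = Z, f = f, i = i, o = o, g = g,
                         C_prev = C, C = Cn, tanhC = tc)
    h <- hn; C <- Cn
  }
  a1 <- add_bias(h %*% params$W1, params$b1)
  r <- pmax(a1, 0)
  p <- softmax(add_bias(r %*% params$W2, params$b2))
  list(p = p, h = h, a1 = a1, r = r, cache = cache)
}

#' Forward pass: sequence to phase probabilities
#'
#' Unrolls the cell over the sequence from zero initial states and maps the
#' final hidden state through the fully connected head and softmax.
#'
#' @param params An `lstm_params`.
#' @param x One sequence (`n x input_size` matrix) or a batch array
#'   (`B x n x input_size`).
#' @param n Expected sequence length (default 5); mismatches error.
#' @return Probability vector of length `n_classes` (rows sum to 1), or a
#'   `B x n_classes` matrix for a batch.
#' @export
lstm_forward <- function(params, x, n = 5L) {
  if (is.matrix(x)) x <- array(x, c(1, dim(x)))
  if (dim(x)[2] != n)
    stop("sequence length ", dim(x)[2], " does not match configured n = ", n)
  if (dim(x)[3] != params$input_size)
    stop("sequence has ", dim(x)[3], " channels; expected ",
         params$input_size)
  p <- lstm_forward_batch(params, x)$p
  if (nrow(p) == 1) as.numeric(p) else p
}

# exact BPTT gradients for a batch; returns mean cross-entropy loss and the
# gradient list matching names(params)
lstm_backward_batch <- function(params, X, Y) {
  B <- dim(X)[1]; n <- dim(X)[2]; H <- params$hidden
  fw <- lstm_forward_batch(params, X, keep_cache = TRUE)
  p <- fw$p
  loss <- -mean(log(pmax(rowSums(p * Y), 1e-300)))
  g <- lapply(params[c("Wf", "bf", "Wi", "bi", "Wo", "bo", "Wc", "bc",
                       "W1", "b1", "W2", "b2")],
              function(w) array(0, dim(w) %||% length(w)))
  da2 <- (p - Y) / B
  g$W2 <- crossprod(fw$r, da2); g$b2 <- colSums(da2)
  dr <- tcrossprod(da2, params$W2)
  da1 <- dr * (fw$a1 > 0)
  g$W1 <- crossprod(fw$h, da1); g$b1 <- colSums(da1)
  dh <- tcrossprod(da1, params$W1)
  dC <- matrix(0, B, H)
  for (t in seq(n, 1L)) {
    cc <- fw$cache[[t]]
    do_ <- dh * cc$tanhC
    dC <- dC + dh * cc$o * (1 - cc$tanhC^2)
    df <- dC * cc$C_prev
    di <- dC * cc$g
    dg <- dC * cc$i
    dC_prev <- dC * cc$f
    dzf <- df * cc$f * (1 - cc$f)
    dzi <- di * cc$i * (1 - cc$i)
    dzo <- do_ * cc$o * (1 - cc$o)
    dzg <- dg * (1 - cc$g^2)
    g$Wf <- g$Wf + crossprod(cc$Z, dzf); g$bf <- g$bf + colSums(dzf)
    g$Wi <- g$Wi + crossprod(cc$Z, dzi); g$bi <- g$bi + colSums(dzi)
    g$Wo <- g$Wo + crossprod(cc$Z, dzo); g$bo <- g$bo + colSums(dzo)
    g$Wc <- g$Wc + crossprod(cc$Z, dzg); g$bc <- g$bc + colSums(dzg)
    dZ <- tcrossprod(dzf, params$Wf) + tcrossprod(dzi, params$Wi) +
      tcrossprod(dzo, params$Wo) + tcrossprod(dzg, params$Wc)
    dh <- dZ[, seq_len(H), drop = FALSE]
    dC <- dC_prev
  }
  list(loss = loss, grads = g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the phase recognizer
#'
#' Mini-batch Adam on categorical cross-entropy with full backpropagation
#' through time. All randomness (initialization, shuffling) derives from
#' `seed`, so a fixed seed reproduces the final weights exactly.
#'
#' @param sequences A `sequence_set` from [make_sequences()] (with targets)
#'   or a `B x n x 30` array.
#' @param targets Target labels (taken from the `sequence_set` if absent).
#' @param classes Class levels in a fixed order; defaults to
#'   [phase_classes()].
#' @param hidden,fc Layer sizes (full-scale defaults 128 and 32; desk-scale
#'   runs use `hidden = 32`).
#' @param epochs Training epochs (default 200 full scale).
#' @param batch Mini-batch size (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Integer seed.
#' @param verbose Print the per-epoch loss.
#' @return An `lstm_model`: list with `params`, `classes`, `n` and
#'   per-epoch `loss`.
#' @export
train_lstm <- function(sequences, targets = NULL, classes = phase_classes(),
                       hidden = 128L, fc = 32L, epochs = 200L, batch = 64L,
                       lr = 1e-3, seed = 1L, verbose = FALSE) {
  if (inherits(sequences, "sequence_set")) {
    if (is.null(targets)) targets <- sequences$y
    n_seq <- sequences$n
    X <- sequences$x
  } else {
    X <- sequences
    n_seq <- dim(X)[2]
  }
  if (epochs < 1) stop("epochs must be >= 1")
  if (batch < 1) stop("batch must be >= 1")
  if (is.null(targets)) stop("targets are required for training")
  if (length(unique(targets)) < 2) stop("need at least 2 classes present")
  absent <- setdiff(classes, unique(targets))
  if (length(absent))
    warning("class(es) absent from training data: ",
            paste(absent, collapse = ", "))
  B_all <- dim(X)[1]
  K <- length(classes)
  Y <- matrix(0, B_all, K)
  Y[cbind(seq_len(B_all), match(targets, classes))] <- 1
  params <- lstm_init(dim(X)[3], hidden, fc, K, seed = seed)
  pn <- c("Wf", "bf", "Wi", "bi", "Wo", "bo", "Wc", "bc",
          "W1", "b1", "W2", "b2")
  m <- lapply(params[pn], function(w) w * 0)
  v <- m
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  step <- 0
  losses <- numeric(epochs)
  with_local_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(B_all)
      tot <- 0
      for (s in seq.int(1L, B_all, by = batch)) {
        rows <- ord[s:min(s + batch - 1L, B_all)]
        bw <- lstm_backward_batch(params,
                                  X[rows, , , drop = FALSE],
                                  Y[rows, , drop = FALSE])
        tot <- tot + bw$loss * length(rows)
        step <- step + 1
        for (nm in pn) {
          m[[nm]] <- b1m * m[[nm]] + (1 - b1m) * bw$grads[[nm]]
          v[[nm]] <- b2m * v[[nm]] + (1 - b2m) * bw$grads[[nm]]^2
          mh <- m[[nm]] / (1 - b1m^step)
          vh <- v[[nm]] / (1 - b2m^step)
          params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
        }
      }
      losses[ep] <- tot / B_all
      if (verbose) message(sprintf("epoch %d loss %.5f", ep, losses[ep]))
    }
  })
  structure(list(params = params, classes = classes, n = n_seq,
                 loss = losses), class = "lstm_model")
}

#' Predict gait phases for sequences
#'
#' Argmax over the forward probabilities; exact ties break toward the
#' lowest class index.
#'
#' @param model An `lstm_model`.
#' @param sequences A `sequence_set` or `B x n x 30` array.
#' @param prob Also return the probability matrix.
#' @return Character vector of phase labels (or list with `label`, `prob`).
#' @export
predict_phase <- function(model, sequences, prob = FALSE) {
  X <- if (inherits(sequences, "sequence_set")) sequences$x else sequences
  if (is.matrix(X)) X <- array(X, c(1, dim(X)))
  P <- matrix(0, dim(X)[1], model$params$n_classes)
  chunk <- 4096L
  for (s in seq.int(1L, dim(X)[1], by = chunk)) {
    rows <- s:min(s + chunk - 1L, dim(X)[1])
    P[rows, ] <- lstm_forward_batch(model$params,
                                    X[rows, , , drop = FALSE])$p
  }
  lab <- model$classes[apply(P, 1, which.max)]  # which.max: lowest index wins
  if (prob) list(label = lab, prob = P) else lab
}

#' @export
print.lstm_model <- function(x, ...) {
  cat("lstm_model:", x$params$hidden, "LSTM units,", x$params$fc,
      "FC units,", x$params$n_classes, "classes, sequence length", x$n,
      "; final loss", signif(utils::tail(x$loss, 1), 4), "\n")
  invisible(x)
}

#' Serialize an LSTM phase model to JSON
#'
#' @param model An `lstm_model`.
#' @param path Output `.json` path.
#' @return `read_phase_model()` returns the `lstm_model`.
#' @export
write_phase_model <- function(model, path) {
  p <- model$params
  mat2list <- function(M) if (is.matrix(M)) apply(M, 1, as.list) else as.list(M)
  ser <- lapply(p[c("Wf", "bf", "Wi", "bi", "Wo", "bo", "Wc", "bc",
                    "W1", "b1", "W2", "b2")], mat2list)
  ser$shape <- p[c("hidden", "input_size", "fc", "n_classes")]
  ser$classes <- model$classes
  ser$n <- model$n
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phase_model
#' @export
read_phase_model <- function(path) {
  raw <- jsonlite::read_json(path)
  list2mat <- function(L) {
    if (is.list(L[[1]])) do.call(rbind, lapply(L, function(r) unlist(r)))
    else unlist(L)
  }
  params <- lapply(raw[c("Wf", "bf", "Wi", "bi", "Wo", "bo", "Wc", "bc",
                         "W1", "b1", "W2", "b2")], list2mat)
  params <- c(params, lapply(raw$shape, as.integer))
  class(params) <- "lstm_params"
  structure(list(params = params, classes = unlist(raw$classes),
                 n = as.integer(raw$n), loss = numeric(0)),
            class = "lstm_model")
}
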