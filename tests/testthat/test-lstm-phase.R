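zero_params <- function(hidden = 4, input = 3) {
  p <- lstm_init(input, hidden, fc = 3, n_classes = 2, seed = 1)
  for (nm in c("Wf", "Wi", "Wo", "Wc")) p[[nm]][] <- 0
  p
}

test_that("the cell update reduces to its closed form at zero weights", {
  p <- zero_params()
  cvec <- c(0.4, -1.2, 2, 0.1)
  out <- cell_step(p, h_prev = rep(0, 4), C_prev = cvec, x = rep(0, 3))
  expect_equal(out$C, 0.5 * cvec, tolerance = 1e-12)        # f = i = 0.5, g = 0
  expect_equal(out$h, 0.5 * tanh(0.5 * cvec), tolerance = 1e-12)
  out0 <- cell_step(p, rep(0, 4), rep(0, 4), rep(1, 3))
  expect_equal(out0$h, rep(0, 4), tolerance = 1e-12)
  expect_error(cell_step(p, rep(0, 3), cvec, rep(0, 3)), "hidden size")
  expect_error(cell_step(p, rep(0, 4), cvec, rep(0, 5)), "input size")
})

test_that("cell_step matches a scalar-by-scalar gate evaluation", {
  sig <- function(z) 1 / (1 + exp(-z))
  set.seed(31)
  for (rep_ in 1:100) {
    p <- lstm_init(input_size = 2, hidden = 3, fc = 2, n_classes = 2,
                   seed = rep_)
    h0 <- rnorm(3); C0 <- rnorm(3); x <- rnorm(2)
    z <- c(h0, x)
    f <- i <- o <- g <- numeric(3)
    for (j in 1:3) {
      f[j] <- sig(sum(z * p$Wf[, j]) + p$bf[j])
      i[j] <- sig(sum(z * p$Wi[, j]) + p$bi[j])
      o[j] <- sig(sum(z * p$Wo[, j]) + p$bo[j])
      g[j] <- tanh(sum(z * p$Wc[, j]) + p$bc[j])
    }
    C1 <- f * C0 + i * g
    h1 <- o * tanh(C1)
    got <- cell_step(p, h0, C0, x)
    expect_lt(max(abs(got$C - C1)), 1e-10)
    expect_lt(max(abs(got$h - h1)), 1e-10)
  }
})

test_that("forward outputs live on the probability simplex", {
  p <- lstm_init(input_size = 30, hidden = 8, fc = 4, n_classes = 6,
                 seed = 3)
  set.seed(3)
  x <- matrix(rnorm(150), 5, 30)
  pr <- lstm_forward(p, x)
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  expect_true(all(pr >= 0))
  expect_error(lstm_forward(p, x[1:4, ]), "length")
  # zero output head gives the uniform distribution
  p$W2[] <- 0; p$b2[] <- 0
  expect_equal(lstm_forward(p, x), rep(1 / 6, 6), tolerance = 1e-12)
})

test_that("forward equals the composition of cell steps and the head", {
  p <- lstm_init(input_size = 3, hidden = 2, fc = 2, n_classes = 3, seed = 7)
  set.seed(7)
  x <- matrix(rnorm(15), 5, 3)
  h <- rep(0, 2); C <- rep(0, 2)
  for (t in 1:5) {
    st <- cell_step(p, h, C, x[t, ])
    h <- st$h; C <- st$C
  }
  a1 <- as.numeric(h %*% p$W1) + p$b1
  r <- pmax(a1, 0)
  a2 <- as.numeric(r %*% p$W2) + p$b2
  oracle <- exp(a2 - max(a2)) / sum(exp(a2 - max(a2)))
  expect_lt(max(abs(lstm_forward(p, x) - oracle)), 1e-10)
})

test_that("backpropagation matches finite differences", {
  p <- lstm_init(input_size = 3, hidden = 4, fc = 3, n_classes = 2, seed = 2)
  set.seed(2)
  X <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
  Y <- rbind(c(1, 0), c(0, 1))
  bw <- gaitrec:::lstm_backward_batch(p, X, Y)
  for (nm in c("Wf", "bf", "Wi", "Wo", "Wc", "bc", "W1", "b1", "W2", "b2")) {
    for (i in c(1L, length(p[[nm]]))) {
      eps <- 1e-6
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      l1 <- gaitrec:::lstm_backward_batch(p2, X, Y)$loss
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      l2 <- gaitrec:::lstm_backward_batch(p2, X, Y)$loss
      expect_lt(abs((l1 - l2) / (2 * eps) - bw$grads[[nm]][i]), 1e-6)
    }
  }
})

test_that("training fits linearly separable toy sequences exactly", {
  set.seed(19)
  n_per <- 40
  mk <- function(mu) array(rnorm(n_per * 5 * 3, mean = mu, sd = 0.3),
                           c(n_per, 5, 3))
  X <- gaitrec:::abind_first(mk(-1), mk(1))
  y <- rep(c("lo", "hi"), each = n_per)
  m <- train_lstm(X, y, classes = c("lo", "hi"), hidden = 6, fc = 4,
                  epochs = 50, batch = 16, seed = 19)
  expect_identical(predict_phase(m, X), y)
  expect_lt(tail(m$loss, 1), head(m$loss, 1))
  expect_error(train_lstm(X, y, classes = c("lo", "hi"), epochs = 0),
               "epochs")
  expect_error(train_lstm(X, rep("lo", 2 * n_per), classes = "lo"),
               "2 classes")
  expect_warning(train_lstm(X, y, classes = c("lo", "hi", "ghost"),
                            hidden = 4, fc = 3, epochs = 1, seed = 1),
                 "ghost")
})

test_that("training with a fixed seed reproduces the weights exactly", {
  set.seed(4)
  X <- array(rnorm(30 * 5 * 3), c(30, 5, 3))
  y <- rep(c("a", "b"), 15)
  m1 <- train_lstm(X, y, classes = c("a", "b"), hidden = 4, fc = 3,
                   epochs = 3, seed = 5)
  m2 <- train_lstm(X, y, classes = c("a", "b"), hidden = 4, fc = 3,
                   epochs = 3, seed = 5)
  expect_identical(m1$params, m2$params)
})

test_that("phase prediction is the argmax with low-index tie-breaking", {
  p <- lstm_init(input_size = 3, hidden = 4, fc = 3, n_classes = 6, seed = 6)
  m <- structure(list(params = p, classes = phase_classes(), n = 5L,
                      loss = numeric(0)), class = "lstm_model")
  set.seed(6)
  X <- array(rnorm(50 * 5 * 3), c(50, 5, 3))
  pred <- predict_phase(m, X)
  P <- lstm_forward(p, X)
  expect_identical(pred, phase_classes()[apply(P, 1, which.max)])
  # engineered tie: uniform output -> first class
  p$W2[] <- 0; p$b2[] <- 0
  m$params <- p
  expect_true(all(predict_phase(m, X) == phase_classes()[1]))
})

test_that("predictions use only the samples inside each window", {
  p <- lstm_init(input_size = 30, hidden = 4, fc = 3, n_classes = 6, seed = 8)
  m <- structure(list(params = p, classes = phase_classes(), n = 5L,
                      loss = numeric(0)), class = "lstm_model")
  set.seed(8)
  s <- make_stream(40, list(waist_gx = rnorm(40)))
  sq1 <- make_sequences(s, n = 5)
  s2 <- s
  s2$waist_gx[21:40] <- 99  # perturb the future
  sq2 <- make_sequences(s2, n = 5)
  # windows ending at or before sample 20 (1-based) are unchanged
  expect_identical(predict_phase(m, sq1$x[1:16, , , drop = FALSE]),
                   predict_phase(m, sq2$x[1:16, , , drop = FALSE]))
})

test_that("phase models survive JSON serialization", {
  set.seed(9)
  X <- array(rnorm(20 * 5 * 3), c(20, 5, 3))
  y <- rep(c("a", "b"), 10)
  m <- train_lstm(X, y, classes = c("a", "b"), hidden = 4, fc = 3,
                  epochs = 2, seed = 9)
  f <- tempfile(fileext = ".json")
  write_phase_model(m, f)
  m2 <- read_phase_model(f)
  expect_identical(predict_phase(m2, X), predict_phase(m, X))
})
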