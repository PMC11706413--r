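random_params <- function(D, H, seed, scale = 0.5) {
  p <- lstm_parameters(D, H, seed = seed)
  set.seed(seed + 1)
  for (nm in c("W_f", "W_i", "W_o", "W_c")) {
    p[[nm]] <- matrix(rnorm((D + H) * H, sd = scale), D + H, H)
  }
  for (nm in c("b_f", "b_i", "b_o", "b_c")) p[[nm]] <- rnorm(H, sd = scale)
  p$W_y <- matrix(rnorm(H * 2, sd = scale), H, 2)
  p$b_y <- rnorm(2, sd = scale)
  p
}

test_that("cell step closed forms: zero weights give half-open gates", {
  D <- 3; H <- 4
  p <- lstm_parameters(D, H, seed = 1)
  for (nm in c("W_f", "W_i", "W_o", "W_c", "W_y")) p[[nm]][] <- 0
  st <- lstm_cell_step(rnorm(D), lstm_state(H), p)
  expect_equal(st$h, rep(0, H))   # tanh(0) kills the candidate
  expect_equal(st$c, rep(0, H))
  expect_identical(st$t, 1L)
  # with carried cell state c: c_t = 0.5 c, h_t = 0.5 tanh(0.5 c)
  s0 <- lstm_state(H); s0$c <- c(1, -2, 0.5, 3)
  st2 <- lstm_cell_step(rnorm(D), s0, p)
  expect_equal(st2$c, 0.5 * s0$c)
  expect_equal(st2$h, 0.5 * tanh(0.5 * s0$c))
})

test_that("cell step matches the scalar-loop oracle over multi-step sequences", {
  set.seed(21)
  worst <- 0
  for (rep_i in 1:25) {
    D <- sample(1:4, 1); H <- sample(1:5, 1)
    p <- random_params(D, H, seed = 300 + rep_i)
    st <- lstm_state(H)
    h <- numeric(H); cc <- numeric(H)
    for (t in 1:4) {
      x <- rnorm(D)
      st <- lstm_cell_step(x, st, p)
      ref <- oracle_lstm_step(x, h, cc, p)
      h <- ref$h; cc <- ref$c
      worst <- max(worst, max(abs(st$h - h)), max(abs(st$c - cc)))
    }
    expect_lt(max(abs(st$h - h)), 1e-10)
  }
  expect_lt(worst, 1e-10)
})

test_that("forward pass yields a proper probability simplex and bounded hidden state", {
  D <- 6; H <- 8
  p <- random_params(D, H, seed = 31)
  out <- lstm_forward(runif(D), p)
  expect_equal(sum(out$probs), 1)
  expect_true(all(out$probs > 0 & out$probs < 1))
  expect_true(all(abs(out$penultimate) <= 1))
  # penultimate equals a single cell step from the zero state
  x <- runif(D)
  st <- lstm_cell_step(x, lstm_state(H), p)
  expect_equal(lstm_forward(x, p)$penultimate, st$h)
  # zero head weights give the uniform distribution
  p0 <- p; p0$W_y[] <- 0; p0$b_y[] <- 0
  expect_equal(lstm_forward(runif(D), p0)$probs, c(0.5, 0.5))
  expect_error(lstm_forward(c(1, NA, 1, 1, 1, 1), p), "non-finite")
  expect_error(lstm_forward(runif(D + 1), p), "does not match")
})

test_that("analytic gradients match central finite differences", {
  D <- 3; H <- 4; B <- 5
  p <- random_params(D, H, seed = 41, scale = 0.4)
  set.seed(42)
  X <- matrix(runif(B * D), B, D)
  y <- c(0L, 1L, 1L, 0L, 1L)
  fw <- pgpm:::lstm_forward_batch(X, p)
  gr <- pgpm:::lstm_backward_batch(fw, y, p)
  loss_at <- function(pp) pgpm:::cross_entropy(pgpm:::lstm_forward_batch(X, pp)$probs, y)
  eps <- 1e-6
  for (nm in c("W_i", "W_o", "W_c", "b_i", "b_o", "b_c", "W_y", "b_y")) {
    idx <- seq_along(p[[nm]])
    probe <- if (length(idx) > 6) sample(idx, 6) else idx
    for (ii in probe) {
      pp <- p; pm <- p
      pp[[nm]][ii] <- pp[[nm]][ii] + eps
      pm[[nm]][ii] <- pm[[nm]][ii] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(unname(gr[[nm]][ii]), num, tolerance = 1e-5)
    }
  }
  # forget-gate gradient vanishes at the zero initial cell state
  expect_true(all(gr$W_f == 0))
})

test_that("training reduces loss, is seed-deterministic, and fits a separable set", {
  set.seed(51)
  n <- 20
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(y * 0.8 + runif(n, 0, 0.2), matrix(runif(n * 3), n, 3))
  colnames(X) <- paste0("f", 1:4)
  fit <- train_lstm_classifier(X, y, epochs = 300, hidden = 8, seed = 7)
  tr <- attr(fit, "loss_trace")
  expect_lt(tr[300], tr[1])
  acc <- mean(as.integer(pgpm:::lstm_predict_proba(fit, X) >= 0.5) == y)
  expect_gte(acc, 0.95)
  fit2 <- train_lstm_classifier(X, y, epochs = 300, hidden = 8, seed = 7)
  expect_identical(attr(fit, "loss_trace"), attr(fit2, "loss_trace"))
  expect_equal(fit$W_y, fit2$W_y)
  expect_error(train_lstm_classifier(X, rep(1, n), seed = 1), "both classes")
  expect_error(train_lstm_classifier(X * 3, y, seed = 1), "normalized")
})

test_that("penultimate features have the contracted shape, bounds and determinism", {
  set.seed(61)
  X <- matrix(runif(8 * 5), 8, 5)
  X[2, ] <- X[1, ]
  p <- random_params(5, 6, seed = 62)
  pen <- extract_penultimate_features(p, X)
  expect_identical(dim(pen), c(8L, 6L))
  expect_true(all(pen >= -1 & pen <= 1))
  expect_equal(pen[1, ], pen[2, ])  # identical inputs, identical features
  expect_error(extract_penultimate_features(p, X[, 1:3]), "expects")
})
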