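#' LSTM parameters
#'
#' Weights of a single LSTM cell plus a 2-class softmax head. Each gate
#' weight matrix has shape `(D + H) x H` and acts on the concatenation
#' `[x_t; h_{t-1}]`; biases have length `H`. Weights are initialized
#' uniformly in `±1/sqrt(H)`, biases at zero.
#'
#' @param D Input size (number of selected taxa).
#' @param H Hidden size (default 32).
#' @param seed Mandatory RNG seed for the initialization.
#' @return An object of class `lstm_parameters`: list with `W_f`, `W_i`,
#'   `W_o`, `W_c` (candidate-context weights), `b_f`, `b_i`, `b_o`, `b_c`,
#'   softmax head `W_y` (`H x 2`), `b_y`, and sizes `D`, `H`.
#' @export
lstm_parameters <- function(D, H = 32, seed) {
  if (missing(seed)) stop("`seed` is mandatory for reproducible initialization", call. = FALSE)
  set.seed(seed)
  r <- 1 / sqrt(H)
  w <- function(nr, nc) matrix(stats::runif(nr * nc, -r, r), nr, nc)
  structure(list(
    W_f = w(D + H, H), W_i = w(D + H, H), W_o = w(D + H, H), W_c = w(D + H, H),
    b_f = numeric(H), b_i = numeric(H), b_o = numeric(H), b_c = numeric(H),
    W_y = w(H, 2), b_y = numeric(2),
    D = D, H = H
  ), class = "lstm_parameters")
}

#' Initial (zero) LSTM state
#'
#' @param H Hidden size.
#' @return An `lstm_state`: list with hidden vector `h`, cell vector `c`
#'   (both zero, length `H`) and step index `t = 0`.
#' @export
lstm_state <- function(H) {
  structure(list(h = numeric(H), c = numeric(H), t = 0L), class = "lstm_state")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One LSTM cell step
#'
#' Computes the forget, input and output gates as logistic sigmoids of
#' affine maps of `[x_t; h_{t-1}]`, the candidate context as the tanh of its
#' affine map, then the cell state `c_t = f * c_{t-1} + i * c_tilde` and the
#' hidden state `h_t = o * tanh(c_t)` (elementwise products). Because
#' `|o| <= 1` and `|tanh| <= 1`, every entry of `h_t` lies in `[-1, 1]`.
#'
#' @param x_t Input vector of length `D`.
#' @param state An [lstm_state()] carrying `h_{t-1}` and `c_{t-1}`.
#' @param params An [lstm_parameters()].
#' @return The updated `lstm_state` (`h_t`, `c_t`, `t + 1`).
#' @export
lstm_cell_step <- function(x_t, state, params) {
  stopifnot(inherits(state, "lstm_state"), inherits(params, "lstm_parameters"))
  if (length(x_t) != params$D) {
    stop(sprintf("input length %d does not match D = %d", length(x_t), params$D), call. = FALSE)
  }
  if (length(state$h) != params$H) stop("state size does not match H", call. = FALSE)
  z <- c(x_t, state$h)
  f <- sigmoid(drop(z %*% params$W_f) + params$b_f)
  i <- sigmoid(drop(z %*% params$W_i) + params$b_i)
  o <- sigmoid(drop(z %*% params$W_o) + params$b_o)
  g <- tanh(drop(z %*% params$W_c) + params$b_c)
  c_t <- f * state$c + i * g
  h_t <- o * tanh(c_t)
  structure(list(h = h_t, c = c_t, t = state$t + 1L), class = "lstm_state")
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

# Vectorized single-step forward over a batch (zero initial state).
# Returns the gate activations needed by the analytic backward pass.
lstm_forward_batch <- function(X, params) {
  B <- nrow(X)
  Z <- cbind(X, matrix(0, B, params$H))
  f <- sigmoid(sweep(Z %*% params$W_f, 2, params$b_f, "+"))
  i <- sigmoid(sweep(Z %*% params$W_i, 2, params$b_i, "+"))
  o <- sigmoid(sweep(Z %*% params$W_o, 2, params$b_o, "+"))
  g <- tanh(sweep(Z %*% params$W_c, 2, params$b_c, "+"))
  C <- i * g                      # f * c0 = 0 at the zero initial state
  Th <- tanh(C)
  Hh <- o * Th
  logits <- sweep(Hh %*% params$W_y, 2, params$b_y, "+")
  list(Z = Z, f = f, i = i, o = o, g = g, C = C, Th = Th, H = Hh,
       logits = logits, probs = softmax_rows(logits))
}

#' LSTM forward pass for one sample
#'
#' Feeds the feature vector as a single time step (T = 1) from the zero
#' initial state through [lstm_cell_step()]; the final hidden state is the
#' penultimate-layer output, and the softmax head turns it into class
#' probabilities.
#'
#' @param x Feature vector of length `D`.
#' @param params An [lstm_parameters()] (cell weights plus softmax head).
#' @return List with `penultimate` (length `H`) and `probs` (length 2,
#'   `c(p_control, p_case)`, summing to 1).
#' @export
lstm_forward <- function(x, params) {
  stopifnot(inherits(params, "lstm_parameters"))
  if (any(!is.finite(x))) stop("input contains non-finite values", call. = FALSE)
  st <- lstm_cell_step(x, lstm_state(params$H), params)
  logits <- drop(st$h %*% params$W_y) + params$b_y
  logits <- logits - max(logits)
  p <- exp(logits) / sum(exp(logits))
  list(penultimate = st$h, probs = p)
}

# Analytic gradients of the mean cross-entropy for the single-step forward.
lstm_backward_batch <- function(fw, Y01, params) {
  B <- nrow(fw$Z)
  Yhot <- cbind(1 - Y01, Y01)
  dlogits <- (fw$probs - Yhot) / B
  dW_y <- crossprod(fw$H, dlogits)
  db_y <- colSums(dlogits)
  dH <- dlogits %*% t(params$W_y)
  dO <- dH * fw$Th
  dC <- dH * fw$o * (1 - fw$Th^2)
  dI <- dC * fw$g
  dG <- dC * fw$i
  dA_o <- dO * fw$o * (1 - fw$o)
  dA_i <- dI * fw$i * (1 - fw$i)
  dA_g <- dG * (1 - fw$g^2)
  # the forget gate multiplies c0 = 0, so its gradient vanishes at T = 1
  list(W_f = matrix(0, nrow(params$W_f), ncol(params$W_f)),
       W_i = crossprod(fw$Z, dA_i),
       W_o = crossprod(fw$Z, dA_o),
       W_c = crossprod(fw$Z, dA_g),
       b_f = numeric(params$H),
       b_i = colSums(dA_i),
       b_o = colSums(dA_o),
       b_c = colSums(dA_g),
       W_y = dW_y, b_y = db_y)
}

cross_entropy <- function(probs, Y01) {
  p <- probs[cbind(seq_along(Y01), Y01 + 1L)]
  -mean(log(pmax(p, 1e-300)))
}

#' Train the LSTM classifier
#'
#' Minimizes the cross-entropy of the softmax head with Adam
#' (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`), reshuffling the samples
#' at the start of every epoch. Gradients are computed analytically for the
#' single-step architecture; the forward pass is exactly [lstm_forward()].
#'
#' @param X Sample x feature matrix, normalized to `[0, 1]`.
#' @param y 0/1 labels; both classes must be present.
#' @param epochs Training epochs (default 300).
#' @param lr Adam learning rate (default 0.001).
#' @param batch Mini-batch size (default 6).
#' @param hidden Hidden size `H` (default 32).
#' @param seed Mandatory RNG seed (initialization and shuffling).
#' @return An `lstm_parameters` object with an added `loss_trace` attribute
#'   (mean training loss per epoch).
#' @export
train_lstm_classifier <- function(X, y, epochs = 300, lr = 0.001, batch = 6,
                                  hidden = 32, seed) {
  stopifnot(is.matrix(X))
  if (missing(seed)) stop("`seed` is mandatory for reproducible training", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present in the training data", call. = FALSE)
  if (min(X) < -1e-9 || max(X) > 1 + 1e-9) {
    stop("inputs must be min-max normalized to [0, 1]", call. = FALSE)
  }
  y <- as.integer(y)
  n <- nrow(X)
  params <- lstm_parameters(ncol(X), hidden, seed = seed)
  tensors <- c("W_f", "W_i", "W_o", "W_c", "b_f", "b_i", "b_o", "b_c", "W_y", "b_y")
  m <- lapply(params[tensors], function(p) p * 0)
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = batch)) {
      b <- idx[start:min(start + batch - 1, n)]
      fw <- lstm_forward_batch(X[b, , drop = FALSE], params)
      losses <- c(losses, cross_entropy(fw$probs, y[b]))
      gr <- lstm_backward_batch(fw, y[b], params)
      step <- step + 1
      for (nm in tensors) {
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gr[[nm]]
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gr[[nm]]^2
        mhat <- m[[nm]] / (1 - b1^step)
        vhat <- v[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    loss_trace[ep] <- mean(losses)
  }
  attr(params, "loss_trace") <- loss_trace
  params
}

#' Extract penultimate-layer features
#'
#' Runs the trained LSTM forward and returns the final hidden state of each
#' sample — the feature vectors handed to the downstream SVM. Entries are
#' bounded in `[-1, 1]`.
#'
#' @param params A trained [lstm_parameters()].
#' @param X Sample x feature matrix with `D` columns.
#' @return Sample x `H` matrix of hidden states.
#' @export
extract_penultimate_features <- function(params, X) {
  stopifnot(inherits(params, "lstm_parameters"), is.matrix(X))
  if (ncol(X) != params$D) {
    stop(sprintf("X has %d features but the model expects %d", ncol(X), params$D), call. = FALSE)
  }
  fw <- lstm_forward_batch(X, params)
  out <- fw$H
  rownames(out) <- rownames(X)
  out
}

# Positive-class (label 1) probability from the softmax head, batched.
lstm_predict_proba <- function(params, X) {
  fw <- lstm_forward_batch(X, params)
  as.numeric(fw$probs[, 2])
}
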