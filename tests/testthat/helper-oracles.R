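# Independent reference implementations used to check the package's
# vectorized code paths. Deliberately written as plain scalar loops / brute
# force so they share nothing with the implementation under test.

# One LSTM step, element by element: gates as sigmoids/tanh of affine maps
# of [x_t; h_prev], then c_t = f*c_prev + i*g and h_t = o*tanh(c_t).
oracle_lstm_step <- function(x, h_prev, c_prev, p) {
  D <- length(x); H <- length(h_prev)
  z <- c(x, h_prev)
  sig <- function(v) 1 / (1 + exp(-v))
  affine <- function(W, b, j) {
    acc <- b[j]
    for (r in seq_len(D + H)) acc <- acc + z[r] * W[r, j]
    acc
  }
  h <- numeric(H); cc <- numeric(H)
  for (j in seq_len(H)) {
    f <- sig(affine(p$W_f, p$b_f, j))
    i <- sig(affine(p$W_i, p$b_i, j))
    o <- sig(affine(p$W_o, p$b_o, j))
    g <- tanh(affine(p$W_c, p$b_c, j))
    cc[j] <- f * c_prev[j] + i * g
    h[j] <- o * tanh(cc[j])
  }
  list(h = h, c = cc)
}

# AUC as the normalized Mann-Whitney pairwise statistic, ties counted 1/2.
oracle_auc_mw <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# PCA contribution scores from a brute-force covariance matrix (pairwise
# sample covariances, n-1 denominator) and a dense eigen-decomposition.
oracle_pca_contribution <- function(X, variance_kept = 0.95) {
  p <- ncol(X)
  C <- matrix(0, p, p)
  for (a in seq_len(p)) for (b in seq_len(p)) {
    C[a, b] <- pgpm::sample_covariance(X[, a], X[, b])
  }
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  evr <- ev / sum(ev)
  m <- which(cumsum(evr) >= variance_kept - 1e-12)[1]
  scores <- numeric(p)
  for (j in seq_len(p)) {
    for (comp in seq_len(m)) scores[j] <- scores[j] + evr[comp] * e$vectors[j, comp]^2
  }
  stats::setNames(scores, colnames(X))
}

# Best achievable Gini impurity decrease of a single axis-aligned split per
# feature (exhaustive over midpoints) — a one-tree stand-in for RF
# importance on tiny toy sets.
oracle_single_split_gini <- function(X, y) {
  gini <- function(lab) {
    if (length(lab) == 0) return(0)
    p <- mean(lab == 1)
    2 * p * (1 - p)
  }
  n <- length(y)
  sapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    cuts <- unique((sort(v)[-1] + sort(v)[-n]) / 2)
    best <- 0
    for (cp in cuts) {
      l <- y[v <= cp]; r <- y[v > cp]
      dec <- gini(y) - (length(l) / n) * gini(l) - (length(r) / n) * gini(r)
      best <- max(best, dec)
    }
    best
  })
}

# Small labelled dataset builders shared across test files.
make_dataset <- function(n = 20, p = 5, seed = 1, separable = FALSE) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:p)))
  y <- rep(c(0, 1), length.out = n)
  if (separable) X[, 1] <- y + runif(n, 0, 0.2)
  labeled_dataset(X, y)
}
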