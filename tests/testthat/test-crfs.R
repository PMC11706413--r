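test_that("sample covariance matches its closed form and symmetry", {
  expect_equal(sample_covariance(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(sample_covariance(c(4, 9, 2), c(5, 5, 5)), 0.0)
  set.seed(3)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(sample_covariance(x, y), sample_covariance(y, x))
  expect_equal(sample_covariance(x, y), stats::cov(x, y))
  expect_error(sample_covariance(1, 1), "at least 2")
})

test_that("RF ranking puts a perfectly separating feature first and zeros constants", {
  set.seed(5)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(sep = y * 2 + runif(n, 0, 0.3),      # perfect separator
             noise = runif(n),
             const = rep(1, n))
  rownames(X) <- sprintf("s%02d", 1:n)
  ds <- labeled_dataset(X, y)

  # independent check that 'sep' really dominates any single split
  gains <- oracle_single_split_gini(X, y)
  expect_identical(which.max(gains), 1L)

  r <- rf_importance_ranking(ds, n_trees = 200, seed = 9)
  expect_identical(r$taxa[1], "sep")
  expect_equal(r$scores[r$taxa == "const"], 0)
  expect_identical(length(r$taxa), ncol(X))
  expect_equal(sum(r$scores), 1)
  # deterministic given the seed
  r2 <- rf_importance_ranking(ds, n_trees = 200, seed = 9)
  expect_identical(r$scores, r2$scores)
  expect_error(rf_importance_ranking(labeled_dataset(X, rep(0, n)), seed = 1),
               "both classes")
})

test_that("PCA contribution matches the brute-force covariance/eigen oracle", {
  set.seed(11)
  for (rep_i in 1:20) {
    n <- sample(3:6, 1); p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%d", 1:n), sprintf("f%d", 1:p)))
    ds <- labeled_dataset(X, rep(c(0, 1), length.out = n))
    r <- pca_contribution_ranking(ds, variance_kept = 0.95)
    oracle <- oracle_pca_contribution(X, 0.95)
    expect_equal(r$scores, as.numeric(oracle[r$taxa]), tolerance = 1e-10)
    # scores sum to the retained explained-variance fraction, <= 1
    expect_lte(sum(r$scores), 1 + 1e-12)
    expect_gte(sum(r$scores), 0.95 - 1e-12)
  }
})

test_that("PCA contribution handles dominant and duplicated features", {
  set.seed(2)
  n <- 12
  big <- rnorm(n, sd = 20)
  X <- cbind(big = big, tiny1 = rnorm(n, sd = 0.01), tiny2 = rnorm(n, sd = 0.01))
  rownames(X) <- sprintf("s%d", 1:n)
  ds <- labeled_dataset(X, rep(c(0, 1), 6))
  r <- pca_contribution_ranking(ds)
  expect_identical(r$taxa[1], "big")
  # two identical features tie
  X2 <- cbind(a = big, b = big, c = rnorm(n))
  rownames(X2) <- rownames(X)
  r2 <- pca_contribution_ranking(labeled_dataset(X2, rep(c(0, 1), 6)))
  expect_equal(r2$scores[r2$taxa == "a"], r2$scores[r2$taxa == "b"], tolerance = 1e-12)
  # zero total variance is an error
  X0 <- matrix(1, 4, 2, dimnames = list(paste0("s", 1:4), c("a", "b")))
  expect_error(pca_contribution_ranking(labeled_dataset(X0, c(0, 1, 0, 1))),
               "zero total variance")
})

test_that("consensus selection intersects top-k prefixes, ordered by RF rank", {
  rf <- new_feature_ranking("rf", c("a", "b", "c", "d"), c(4, 3, 2, 1))
  pca <- new_feature_ranking("pca", c("c", "b", "x", "y"), c(4, 3, 2, 1))
  sel <- consensus_select(rf, pca, k = 2)
  expect_identical(sel$selected, "b")
  sel3 <- consensus_select(rf, pca, k = 3)
  expect_identical(sel3$selected, c("b", "c"))  # RF order, not PCA order
  # identical rankings select everything
  expect_identical(consensus_select(rf, rf, k = 4)$selected, c("a", "b", "c", "d"))
  # disjoint lists are an error telling the caller to raise k
  pca2 <- new_feature_ranking("pca", c("x", "y", "z", "w"), c(4, 3, 2, 1))
  expect_error(consensus_select(rf, pca2, k = 2), "raise k")
  expect_error(consensus_select(rf, pca, k = 5), "exceeds")
})

test_that("consensus is stable under sub-rank score perturbations", {
  set.seed(7)
  taxa_names <- sprintf("t%02d", 1:30)
  s1 <- sort(runif(30), decreasing = TRUE)
  s2 <- sort(runif(30), decreasing = TRUE)
  perm <- sample(30)
  r1 <- new_feature_ranking("rf", taxa_names, s1)
  r2 <- new_feature_ranking("pca", taxa_names[perm], s2)
  base <- consensus_select(r1, r2, k = 10)$selected
  eps <- min(abs(diff(s1)), abs(diff(s2))) / 3
  r1p <- new_feature_ranking("rf", r1$taxa, r1$scores + runif(30, -eps, eps))
  r2p <- new_feature_ranking("pca", r2$taxa, r2$scores + runif(30, -eps, eps))
  expect_identical(consensus_select(r1p, r2p, k = 10)$selected, base)
})

test_that("min-max normalization maps to [0,1], is idempotent and rank-preserving", {
  expect_equal(minmax_normalize(cbind(a = c(0, 5, 10)))$X[, "a"], c(0, 0.5, 1))
  expect_equal(minmax_normalize(cbind(a = c(3, 3, 3)))$X[, "a"], c(0, 0, 0))
  set.seed(13)
  X <- matrix(rnorm(40, 10, 4), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  nm <- minmax_normalize(X)
  expect_true(all(nm$X >= 0 & nm$X <= 1))
  expect_equal(apply(nm$X, 2, min), rep(0, 4), ignore_attr = TRUE)
  expect_equal(apply(nm$X, 2, max), rep(1, 4), ignore_attr = TRUE)
  # rank order preserved within feature
  for (j in 1:4) expect_identical(order(nm$X[, j]), order(X[, j]))
  # idempotent on [0,1]-spanning columns
  expect_equal(minmax_normalize(nm$X)$X, nm$X)
  # held-out application clips to [0, 1]
  out <- apply_minmax(X + 100, nm$ranges)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("consensus selection recovers planted taxa on synthetic cohorts", {
  hits <- sapply(1:2, function(s) {
    co <- generate_cohort(cohort_spec(60, 60, 120, 8, effect_logfold = 2,
                                      seed = 100 + s))
    ds <- attach_labels(transpose_to_samples(co$table), co$labels)
    sel <- consensus_select(rf_importance_ranking(ds, 300, seed = s),
                            pca_contribution_ranking(ds), k = 20)
    sum(co$truth$taxon %in% sel$selected)
  })
  expect_true(all(hits >= 6))
})
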