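test_that("cohort specs validate their fields", {
  expect_error(cohort_spec(10, 10, 5, 8, seed = 1), "n_informative")
  expect_error(cohort_spec(10, 10, 50, 8, sparsity = 1, seed = 1), "sparsity")
  expect_error(cohort_spec(10, 10, 50, 8, effect_logfold = Inf, seed = 1), "finite")
  expect_error(cohort_spec(10, 10, 50, 8), "seed")
  sp <- default_study_spec(seed = 4)
  expect_equal(sp$n_cases + sp$n_controls, 78)
  expect_equal(sp$n_informative, 8)
  expect_s3_class(sp, "cohort_spec")
})

test_that("generated cohorts honour closure, orientation, seed and non-negativity", {
  sp <- cohort_spec(15, 12, 60, 5, seed = 33)
  co <- generate_cohort(sp)
  expect_identical(co$table$orientation, "taxa_as_rows")
  expect_identical(dim(co$table$values), c(60L, 27L))
  expect_true(all(co$table$values >= 0))
  expect_equal(colSums(co$table$values), rep(1, 27), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(sum(co$labels == 1), 15L)
  expect_identical(nrow(co$truth), 5L)
  expect_true(all(co$truth$taxon %in% taxa(co$table)))
  # same seed, bit-identical output
  co2 <- generate_cohort(sp)
  expect_identical(co$table$values, co2$table$values)
})

test_that("sparsity rate is honoured at scale", {
  sp <- cohort_spec(30, 30, 200, 8, sparsity = 0.3, closure = FALSE, seed = 44)
  co <- generate_cohort(sp)
  expect_equal(mean(co$table$values == 0), 0.3, tolerance = 0.02)
})

test_that("the planted log-fold effect is recovered empirically", {
  diffs <- sapply(1:10, function(s) {
    sp <- cohort_spec(200, 200, 50, 6, effect_logfold = 1.0, sparsity = 0,
                      closure = FALSE, seed = 500 + s)
    co <- generate_cohort(sp)
    lv <- log(co$table$values[co$truth$taxon, , drop = FALSE])
    mean(rowMeans(lv[, co$labels == 1]) - rowMeans(lv[, co$labels == 0]))
  })
  expect_true(all(abs(diffs - 1.0) < 0.15))
})

test_that("effect size drives separability monotonically, with a null at zero effect", {
  aucs <- sapply(c(0, 0.5, 1.5), function(eff) {
    co <- generate_cohort(cohort_spec(40, 40, 80, 8, effect_logfold = eff, seed = 77))
    ds <- attach_labels(transpose_to_samples(co$table), co$labels)
    # at zero effect the consensus can legitimately be empty; fall back to
    # all taxa so the null model still runs
    cfg <- pgpm_config(k_folds = 5, n_trees = 200, epochs = 40, hidden = 16,
                       top_k = 40, seed = 88)
    run_cv(ds, cfg)$auc
  })
  expect_gte(aucs[3], 0.85)
  expect_gt(aucs[3], aucs[1])
  expect_gte(aucs[2], aucs[1] - 0.1)  # intermediate effect is not worse than null
  expect_true(aucs[1] > 0.25 && aucs[1] < 0.75)  # null band
})

test_that("label permutation destroys the signal", {
  set.seed(99)
  aucs <- sapply(1:3, function(s) {
    co <- generate_cohort(cohort_spec(40, 40, 80, 8, effect_logfold = 1.5,
                                      seed = 600 + s))
    ds <- attach_labels(transpose_to_samples(co$table), co$labels)
    yp <- sample(ds$y)
    dsp <- labeled_dataset(ds$X, yp)
    cfg <- pgpm_config(k_folds = 5, n_trees = 200, epochs = 40, hidden = 16,
                       seed = 700 + s)
    run_cv(dsp, cfg)$auc
  })
  expect_true(all(aucs > 0.25 & aucs < 0.75))
})
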