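#' Soft-vote configuration
#'
#' @param w_lstm,w_svm Non-negative voter weights; they are normalized to
#'   sum to 1.
#' @param threshold Decision threshold tau in (0, 1); a sample is called a
#'   case when the fused probability is `>= threshold` (default 0.5).
#' @return A `vote_config`.
#' @export
vote_config <- function(w_lstm = 0.5, w_svm = 0.5, threshold = 0.5) {
  if (w_lstm < 0 || w_svm < 0 || w_lstm + w_svm <= 0) {
    stop("weights must be non-negative and not both zero", call. = FALSE)
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)", call. = FALSE)
  s <- w_lstm + w_svm
  structure(list(w_lstm = w_lstm / s, w_svm = w_svm / s, threshold = threshold),
            class = "vote_config")
}

#' Soft-vote fusion of the two LSIM probabilities
#'
#' `p_final = w_lstm * p_lstm + w_svm * p_svm`; the label is 1 when
#' `p_final >= threshold`.
#'
#' @param p_lstm,p_svm Probabilities in `[0, 1]` (vectorized).
#' @param cfg A [vote_config()].
#' @return List with `p_final` and integer `label`.
#' @export
soft_vote <- function(p_lstm, p_svm, cfg = vote_config()) {
  stopifnot(inherits(cfg, "vote_config"), length(p_lstm) == length(p_svm))
  if (any(p_lstm < 0 | p_lstm > 1 | p_svm < 0 | p_svm > 1)) {
    stop("vote inputs must be probabilities in [0, 1]", call. = FALSE)
  }
  p <- cfg$w_lstm * p_lstm + cfg$w_svm * p_svm
  list(p_final = p, label = as.integer(p >= cfg$threshold))
}

#' Assign samples to cross-validation folds
#'
#' Shuffled partition into `k` folds whose sizes differ by at most one;
#' each fold serves once as the held-out test set. With `y` supplied the
#' split is stratified: each class is spread as evenly as possible across
#' folds, which avoids single-class training folds in small balanced
#' cohorts. With `pairs` supplied (e.g. patient/spouse couple ids), members
#' of a pair are kept in the same fold.
#'
#' @param n Number of samples (`n >= k`).
#' @param k Number of folds (default 10).
#' @param seed Mandatory RNG seed.
#' @param y Optional 0/1 labels for stratification.
#' @param pairs Optional vector of pair/group ids of length `n`.
#' @return Integer vector of fold indices in `1..k`, one per sample.
#' @export
kfold_split <- function(n, k = 10, seed, y = NULL, pairs = NULL) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop(sprintf("cannot split n = %d samples into k = %d folds", n, k), call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  if (!is.null(pairs)) {
    stopifnot(length(pairs) == n)
    groups <- sample(unique(pairs))
    gf <- rep_len(seq_len(k), length(groups))
    fold <- gf[match(pairs, groups)]
  } else if (!is.null(y)) {
    stopifnot(length(y) == n)
    # cyclic assignment over the class-blocked shuffled sequence keeps both
    # overall and per-class fold sizes within one of each other
    idx <- unlist(lapply(unique(y), function(cl) sample(which(y == cl))))
    fold[idx] <- rep_len(seq_len(k), n)
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with the defaults used
#' throughout: 10-fold CV, top-20 consensus selection, 500-tree forests,
#' 95% PCA variance kept, LSTM with H = 32 trained 300 epochs at lr 0.001
#' in batches of 6, SVM cost 1, equal-weight soft vote at threshold 0.5.
#'
#' @param k_folds,top_k,n_trees,variance_kept,epochs,lr,batch,hidden,cost
#'   See module functions.
#' @param vote A [vote_config()].
#' @param paper_mode When TRUE, consensus selection is performed once on the
#'   full dataset before splitting (the protocol as originally described);
#'   when FALSE (default) selection is re-fit inside every training fold,
#'   which avoids test-fold leakage.
#' @param seed Mandatory master seed; all fold-level seeds derive from it.
#' @return A `pgpm_config` list.
#' @export
pgpm_config <- function(k_folds = 10, top_k = 20, n_trees = 500,
                        variance_kept = 0.95, epochs = 300, lr = 0.001,
                        batch = 6, hidden = 32, cost = 1,
                        vote = vote_config(), paper_mode = FALSE, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  structure(list(k_folds = k_folds, top_k = top_k, n_trees = n_trees,
                 variance_kept = variance_kept, epochs = epochs, lr = lr,
                 batch = batch, hidden = hidden, cost = cost, vote = vote,
                 paper_mode = paper_mode, seed = as.integer(seed)),
            class = "pgpm_config")
}

select_features <- function(data, config, seed) {
  r_rf <- rf_importance_ranking(data, n_trees = config$n_trees, seed = seed)
  r_pca <- pca_contribution_ranking(data, variance_kept = config$variance_kept)
  consensus_select(r_rf, r_pca, k = config$top_k)
}

#' Cross-validated evaluation of the full pipeline
#'
#' For each fold: consensus feature selection on the training fold (or once
#' on the full data in `paper_mode`), min-max normalization learned on the
#' training fold and applied clipped to the test fold, LSIM fit, the two
#' probability readings on the test fold, and soft-vote fusion. Fold
#' accuracies, pooled out-of-fold predictions, the pooled ROC curve and its
#' AUC are accumulated. Every source of randomness derives from
#' `config$seed`, so a re-run with the same configuration reproduces every
#' prediction exactly.
#'
#' @param data A [labeled_dataset()] with all candidate taxa as features.
#' @param config A [pgpm_config()].
#' @return A `cv_report`: `fold_acc` (length k), `mean_acc`, `predictions`
#'   (one out-of-fold row per sample: `sample_id`, `fold`, `y`, `p_lstm`,
#'   `p_svm`, `p_final`, `label`), `roc`, `auc`, `selected` (per-fold list
#'   of selected taxa), `config`.
#' @export
run_cv <- function(data, config) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(config, "pgpm_config"))
  n <- nrow(data$X)
  k <- config$k_folds
  if (n < 2 * k) stop(sprintf("need n >= 2k samples (n = %d, k = %d)", n, k), call. = FALSE)

  set.seed(config$seed)
  fold_seeds <- sample.int(.Machine$integer.max - 1, k)
  selection_seed <- sample.int(.Machine$integer.max - 1, 1)
  fold <- kfold_split(n, k, seed = config$seed, y = data$y)

  full_selection <- if (config$paper_mode) select_features(data, config, selection_seed)

  ids <- if (!is.null(data$sample_ids)) data$sample_ids else as.character(seq_len(n))
  preds <- data.frame(sample_id = ids, fold = fold, y = data$y,
                      p_lstm = NA_real_, p_svm = NA_real_,
                      p_final = NA_real_, label = NA_integer_)
  fold_acc <- numeric(k)
  selected <- vector("list", k)

  for (f in seq_len(k)) {
    te <- fold == f
    ytr <- data$y[!te]
    if (length(unique(ytr)) < 2) {
      stop(sprintf("training data of fold %d contains a single class", f), call. = FALSE)
    }
    train_all <- labeled_dataset(data$X[!te, , drop = FALSE], ytr)
    sel <- if (config$paper_mode) full_selection else {
      select_features(train_all, config, fold_seeds[f])
    }
    selected[[f]] <- sel$selected

    Xtr <- data$X[!te, sel$selected, drop = FALSE]
    norm <- minmax_normalize(Xtr)
    Xte <- apply_minmax(data$X[te, sel$selected, drop = FALSE], norm$ranges, clip = TRUE)

    model <- lsim_fit(labeled_dataset(norm$X, ytr),
                      epochs = config$epochs, lr = config$lr,
                      batch = config$batch, hidden = config$hidden,
                      cost = config$cost, seed = fold_seeds[f])
    pp <- lsim_predict_proba(model, Xte)
    vote <- soft_vote(pp$p_lstm, pp$p_svm, config$vote)

    preds$p_lstm[te] <- pp$p_lstm
    preds$p_svm[te] <- pp$p_svm
    preds$p_final[te] <- vote$p_final
    preds$label[te] <- vote$label
    fold_acc[f] <- accuracy(confusion_counts(vote$label, data$y[te]))
  }

  roc <- roc_curve(preds$p_final, preds$y)
  structure(list(fold_acc = fold_acc, mean_acc = mean(fold_acc),
                 predictions = preds, roc = roc, auc = auc_trapezoid(roc),
                 selected = selected, config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV on %d samples\n", x$config$k_folds, nrow(x$predictions)))
  cat(sprintf("  mean ACC: %.3f   pooled AUC: %.3f\n", x$mean_acc, x$auc))
  cat("  fold ACC:", paste(sprintf("%.2f", x$fold_acc), collapse = " "), "\n")
  invisible(x)
}

#' Write a CV report as JSON (plus optional ROC points)
#'
#' @param report A [run_cv()] result.
#' @param path Output JSON path.
#' @param roc_path Optional path for the ROC points as delimited text.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path, roc_path = NULL) {
  stopifnot(inherits(report, "cv_report"))
  obj <- list(mean_acc = report$mean_acc, auc = report$auc,
              fold_acc = report$fold_acc,
              selected = report$selected,
              predictions = report$predictions)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  if (!is.null(roc_path)) write_roc(report$roc, roc_path)
  invisible(path)
}
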