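#' Sample covariance of two vectors
#'
#' The covariance that underlies the principal-component decomposition used
#' for feature ranking: `sum((x - mean(x)) * (y - mean(y))) / (n - 1)`.
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @return The sample covariance (a scalar).
#' @export
sample_covariance <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 2) stop("need at least 2 observations (denominator n - 1)", call. = FALSE)
  sum((x - mean(x)) * (y - mean(y))) / (n - 1)
}

new_feature_ranking <- function(method, taxa, scores, k_available = length(taxa)) {
  stopifnot(length(taxa) == length(scores), all(is.finite(scores)))
  ord <- order(-scores, taxa)  # ties broken by taxon name for determinism
  structure(list(method = method,
                 taxa = taxa[ord],
                 scores = scores[ord],
                 k_available = k_available),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, n = 10, ...) {
  cat(sprintf("<feature_ranking> method: %s, %d taxa\n", x$method, length(x$taxa)))
  print(utils::head(data.frame(taxon = x$taxa, score = x$scores), n))
  invisible(x)
}

#' Rank taxa by random-forest importance
#'
#' Fits a classification random forest of the disease label on all taxa and
#' ranks taxa by mean decrease in Gini impurity, normalized to sum to 1.
#' Constant features are never chosen for a split and receive importance 0.
#'
#' @param data A [labeled_dataset()] with both classes present.
#' @param n_trees Number of trees (default 500).
#' @param seed Mandatory RNG seed; the ranking is deterministic given it.
#' @return A `feature_ranking` with `method = "rf"`.
#' @export
rf_importance_ranking <- function(data, n_trees = 500, seed) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (missing(seed)) stop("`seed` is mandatory for a reproducible ranking", call. = FALSE)
  if (length(unique(data$y)) < 2) stop("both classes must be present", call. = FALSE)
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  set.seed(seed)
  fit <- randomForest::randomForest(x = data$X,
                                    y = factor(data$y, levels = c(0, 1)),
                                    ntree = n_trees)
  imp <- fit$importance[, "MeanDecreaseGini"]
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  new_feature_ranking("rf", data$feature_names, as.numeric(imp))
}

#' Rank taxa by principal-component contribution
#'
#' Unsupervised ranking: features are centred (not scaled), decomposed by
#' PCA, and each taxon scored by the explained-variance-ratio-weighted sum
#' of its squared loadings over the components retained to reach
#' `variance_kept` cumulative explained variance. The scores of all taxa sum
#' to the retained explained-variance fraction.
#'
#' @param data A [labeled_dataset()]; labels are ignored.
#' @param variance_kept Fraction of total variance the retained components
#'   must explain (default 0.95).
#' @return A `feature_ranking` with `method = "pca"`.
#' @export
pca_contribution_ranking <- function(data, variance_kept = 0.95) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (nrow(data$X) < 2) stop("need at least 2 samples", call. = FALSE)
  pc <- stats::prcomp(data$X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  tot <- sum(ev)
  if (tot <= 0) stop("zero total variance; cannot rank by PCA contribution", call. = FALSE)
  evr <- ev / tot
  m <- which(cumsum(evr) >= variance_kept - 1e-12)[1]
  if (is.na(m)) m <- length(evr)
  load2 <- pc$rotation[, seq_len(m), drop = FALSE]^2
  scores <- as.numeric(load2 %*% evr[seq_len(m)])
  new_feature_ranking("pca", data$feature_names, scores)
}

#' Consensus feature selection from two rankings
#'
#' The CRFS selection rule: intersect the top-`k` taxa of the random-forest
#' ranking with the top-`k` taxa of the PCA-contribution ranking. The
#' intersection is returned ordered by random-forest rank.
#'
#' @param r_rf,r_pca `feature_ranking` objects (conventionally the RF and
#'   PCA rankings; the first supplies the output order).
#' @param k Size of each top list (default 20).
#' @return A `consensus_selection` with fields `selected`, `k`,
#'   `source_rankings`.
#' @export
consensus_select <- function(r_rf, r_pca, k = 20) {
  stopifnot(inherits(r_rf, "feature_ranking"), inherits(r_pca, "feature_ranking"))
  if (k > r_rf$k_available || k > r_pca$k_available) {
    stop(sprintf("k = %d exceeds the available list sizes (%d, %d)",
                 k, r_rf$k_available, r_pca$k_available), call. = FALSE)
  }
  top_rf <- r_rf$taxa[seq_len(k)]
  top_pca <- r_pca$taxa[seq_len(k)]
  selected <- top_rf[top_rf %in% top_pca]  # ordered by RF rank
  if (length(selected) == 0) {
    stop(sprintf("the two top-%d lists share no taxa; raise k to obtain a non-empty consensus", k),
         call. = FALSE)
  }
  structure(list(selected = selected, k = k,
                 source_rankings = list(rf = r_rf, pca = r_pca)),
            class = "consensus_selection")
}

#' @export
print.consensus_selection <- function(x, ...) {
  cat(sprintf("<consensus_selection> %d of top-%d taxa shared:\n", length(x$selected), x$k))
  cat(paste0("  ", x$selected, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a selection report
#'
#' One row per taxon in the union of the two rankings, with each method's
#' rank and score and whether the taxon made the consensus.
#'
#' @param selection A [consensus_select()] result.
#' @param path Output path.
#' @param delimiter Field delimiter; TAB by default.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(selection, path, delimiter = "\t") {
  stopifnot(inherits(selection, "consensus_selection"))
  rf <- selection$source_rankings$rf
  pca <- selection$source_rankings$pca
  all_taxa <- union(rf$taxa, pca$taxa)
  df <- data.frame(
    taxon = all_taxa,
    rf_rank = match(all_taxa, rf$taxa),
    rf_score = rf$scores[match(all_taxa, rf$taxa)],
    pca_rank = match(all_taxa, pca$taxa),
    pca_score = pca$scores[match(all_taxa, pca$taxa)],
    selected = all_taxa %in% selection$selected
  )
  df <- df[order(df$rf_rank), ]
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Min-max normalize a matrix per feature
#'
#' Maps every feature to `[0, 1]` by `x' = (x - Min) / (Max - Min)` with the
#' per-feature Min and Max. Constant features (Max = Min) map to all zeros:
#' they carry no signal and 0/0 is avoided.
#'
#' @param X Sample x feature numeric matrix with finite entries.
#' @return A `normalized_matrix`: list with `X` (the transformed matrix) and
#'   `ranges` (2 x feature matrix of the Min and Max used).
#' @export
minmax_normalize <- function(X) {
  stopifnot(is.matrix(X), all(is.finite(X)))
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  out <- apply_minmax(X, rbind(min = mins, max = maxs), clip = FALSE)
  structure(list(X = out, ranges = rbind(min = mins, max = maxs)),
            class = "normalized_matrix")
}

#' Apply stored min-max ranges to new data
#'
#' Used on held-out folds: the (Min, Max) learned on the training fold are
#' applied and, optionally, results clipped to `[0, 1]` so test values
#' outside the training range cannot leak outside the model's input domain.
#'
#' @param X Sample x feature numeric matrix.
#' @param ranges 2 x feature matrix (`min`, `max` rows) as produced by
#'   [minmax_normalize()].
#' @param clip Clip the result to `[0, 1]` (default TRUE).
#' @return Transformed matrix.
#' @export
apply_minmax <- function(X, ranges, clip = TRUE) {
  stopifnot(is.matrix(X), ncol(X) == ncol(ranges))
  span <- ranges["max", ] - ranges["min", ]
  out <- sweep(X, 2, ranges["min", ], "-")
  nz <- span > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, span[nz], "/")
  out[, !nz] <- 0
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}
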