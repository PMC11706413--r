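#' Published top-20 taxon rankings (worked example)
#'
#' The two ranked species lists reported for the original 39 PD / 39 spouse
#' cohort — the top 20 taxa by random-forest importance and the top 20 by
#' PCA contribution — packaged as a worked example for
#' [consensus_select()]. Only ranks were published, so scores are encoded as
#' `k_available - rank + 1`, which preserves the ordering; the underlying
#' feature universe is larger than the 20 published entries, so
#' `k_available` is 20 for both lists.
#'
#' @return List with `feature_ranking` objects `rf` and `pca`.
#' @export
published_crfs_rankings <- function() {
  path <- system.file("extdata", "published_top20_rankings.tsv",
                      package = "pgpm", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  k <- nrow(df)
  list(
    rf = new_feature_ranking("rf", df$rf_species, k - df$rank + 1, k_available = k),
    pca = new_feature_ranking("pca", df$pca_species, k - df$rank + 1, k_available = k)
  )
}
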