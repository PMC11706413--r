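#' Specification of a synthetic case/control cohort
#'
#' Describes a cohort of non-negative species abundances with a small set of
#' planted differentially abundant taxa. Baseline log-abundances are normal
#' (`base_log_mean`, `base_log_sd`); in cases, each informative taxon's log
#' mean is shifted by `effect_logfold` in a planted direction (+1 enriched,
#' -1 depleted). Structural zeros are placed uniformly at rate `sparsity`
#' before optional closure to per-sample relative abundances.
#'
#' @param n_cases,n_controls Group sizes.
#' @param n_taxa Total number of taxa.
#' @param n_informative Number of planted differential taxa
#'   (`<= n_taxa`).
#' @param effect_logfold Mean log-abundance shift (natural log) of
#'   informative taxa in cases.
#' @param base_log_mean,base_log_sd Baseline log-normal parameters.
#' @param sparsity Fraction of structural zeros in `[0, 1)`.
#' @param closure Renormalize each sample to sum to 1 (relative abundances).
#' @param seed Mandatory RNG seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, n_taxa, n_informative,
                        effect_logfold = 1.0, base_log_mean = 0,
                        base_log_sd = 1.0, sparsity = 0.3, closure = TRUE,
                        seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (n_informative > n_taxa) stop("n_informative must be <= n_taxa", call. = FALSE)
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must lie in [0, 1)", call. = FALSE)
  if (!is.finite(effect_logfold)) stop("effect_logfold must be finite", call. = FALSE)
  if (n_cases < 1 || n_controls < 1) stop("both groups need at least one sample", call. = FALSE)
  structure(list(n_cases = n_cases, n_controls = n_controls, n_taxa = n_taxa,
                 n_informative = n_informative, effect_logfold = effect_logfold,
                 base_log_mean = base_log_mean, base_log_sd = base_log_sd,
                 sparsity = sparsity, closure = closure, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default cohort specification mirroring the study design
#'
#' 39 cases and 39 controls (patients and their healthy spouses), 200 taxa,
#' 8 planted differential taxa — the size of the consensus-selected feature
#' set — with a unit log-fold effect.
#'
#' @param seed Mandatory RNG seed.
#' @return A [cohort_spec()].
#' @export
default_study_spec <- function(seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  cohort_spec(n_cases = 39, n_controls = 39, n_taxa = 200, n_informative = 8,
              effect_logfold = 1.0, seed = seed)
}

#' Generate a synthetic case/control cohort
#'
#' Draws the cohort described by a [cohort_spec()]. The abundance table is
#' emitted in the profiler-native `taxa_as_rows` orientation; cases are
#' labelled 1, controls 0. Informative taxa are a seeded random subset, each
#' shifted by `effect_logfold` in cases; the planted direction recorded in
#' the ground truth is the sign of the shift.
#'
#' @param spec A [cohort_spec()].
#' @return List with `table` (an [abundance_table()]), `labels` (named 0/1
#'   vector) and `truth` (data.frame `taxon`, `direction`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_cases + spec$n_controls
  taxa_names <- sprintf("taxon_%03d", seq_len(spec$n_taxa))
  sample_ids <- c(sprintf("PD_%03d", seq_len(spec$n_cases)),
                  sprintf("SP_%03d", seq_len(spec$n_controls)))
  y <- stats::setNames(c(rep(1, spec$n_cases), rep(0, spec$n_controls)), sample_ids)

  informative <- sort(sample.int(spec$n_taxa, spec$n_informative))
  direction <- rep_len(sign(spec$effect_logfold), spec$n_informative)

  mu <- matrix(spec$base_log_mean, nrow = spec$n_taxa, ncol = n,
               dimnames = list(taxa_names, sample_ids))
  mu[informative, y == 1] <- mu[informative, y == 1] + spec$effect_logfold
  vals <- exp(mu + matrix(stats::rnorm(spec$n_taxa * n, 0, spec$base_log_sd),
                          spec$n_taxa, n))

  if (spec$sparsity > 0) {
    zero <- matrix(stats::runif(spec$n_taxa * n) < spec$sparsity, spec$n_taxa, n)
    vals[zero] <- 0
  }
  if (spec$closure) {
    cs <- colSums(vals)
    cs[cs == 0] <- 1  # guard: an all-zero sample stays all-zero
    vals <- sweep(vals, 2, cs, "/")
  }

  list(table = abundance_table(vals, "taxa_as_rows"),
       labels = y,
       truth = data.frame(taxon = taxa_names[informative],
                          direction = direction))
}
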