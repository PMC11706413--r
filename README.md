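# pgpm

Predicting Parkinson's disease (PD) status from species-level gut-microbiome
profiles. Case/control studies of the gut–brain axis produce relative-abundance
tables with a few dozen subjects and hundreds of taxa; `pgpm` packages a
complete pipeline for turning such a table plus binary disease labels into a
cross-validated classifier and honest performance estimates, together with a
synthetic cohort generator so every stage can be exercised without access to
patient data.

## The method

The pipeline has three stages:

1. **CRFS consensus feature selection.** Taxa are ranked two ways on the
   training data: by random-forest importance (mean decrease in Gini impurity
   over 500 trees, normalized to sum to 1) and by PCA contribution — each
   taxon's explained-variance-ratio-weighted sum of squared loadings over the
   principal components retained to cover 95% of variance, computed from the
   sample covariance `cov(X,Y) = Σ(Xᵢ−X̄)(Yᵢ−Ȳ)/(n−1)`. The selected features
   are the **intersection of the two top-20 lists**, ordered by RF rank. The
   selected columns are min-max normalized per feature,
   `x′ = (x − Min)/(Max − Min)`.

2. **LSIM hybrid classification.** The normalized feature vector is fed as a
   single time step to an LSTM cell (gates `f, i, o = σ(W[x; h] + b)`,
   candidate context `c̃ = tanh(·)`, `cₜ = f⊙cₜ₋₁ + i⊙c̃`, `hₜ = o⊙tanh(cₜ)`,
   hidden size 32) with a 2-class softmax head, trained with cross-entropy and
   Adam (300 epochs, lr 0.001, batch 6, per-epoch reshuffling). The
   **penultimate layer** — the final hidden state — becomes the input of an
   RBF-kernel SVM, `K(x,y) = exp(−γ‖x−y‖²)` with the variance-scaled
   bandwidth `γ = 1/(n_features · Var(X))`, whose decision values are
   calibrated to probabilities by a Platt sigmoid.

3. **Soft voting.** The LSTM softmax probability and the calibrated SVM
   probability are averaged (configurable weights) and thresholded at 0.5.

Evaluation is stratified 10-fold cross-validation: per-fold accuracy, pooled
out-of-fold ROC curve and trapezoid AUC (equal to the Mann–Whitney
probability that a random case outscores a random control). Note one
deliberate deviation from the formula sheet this method descends from: the
false-positive rate is computed as the standard `FP/(FP+TN)` — the published
`FP/(TP+TN)` form is not a rate over negatives and breaks ROC semantics.

By default feature selection is re-fit **inside every training fold** to
avoid test-set leakage; `paper_mode = TRUE` restores the original protocol of
selecting once on the full dataset before splitting.

## Worked example

The consensus rule on the two published top-20 species rankings from the
original 39 PD / 39 healthy-spouse cohort (packaged in
`inst/extdata/published_top20_rankings.tsv`):

```r
library(pgpm)
r <- published_crfs_rankings()
consensus_select(r$rf, r$pca, k = 20)
#> <consensus_selection> 8 of top-20 taxa shared:
#>   Bifidobacterium_dentium
#>   Alistipes_putredinis
#>   Alistipes_indistinctus
#>   Scardovia_wiggsiae
#>   Gemella_haemolysans
#>   Bacteroides_coprocola
#>   Parabacteroides_goldsteinii
#>   Lactobacillus_salivarius
```

The eight shared taxa, ordered by random-forest rank, are exactly the input
features of the downstream classifier.

End-to-end on a synthetic cohort (100 cases / 100 controls, 200 taxa, 8
planted differential taxa at a 1.5 natural-log-fold effect):

```r
spec <- default_study_spec(seed = 1)
spec$n_cases <- 100; spec$n_controls <- 100; spec$effect_logfold <- 1.5
cohort <- generate_cohort(spec)
data <- attach_labels(transpose_to_samples(cohort$table), cohort$labels)
report <- run_cv(data, pgpm_config(epochs = 100, seed = 1))
report
#> <cv_report> 10-fold CV on 200 samples
#>   mean ACC: 0.905   pooled AUC: 0.956
#>   fold ACC: 0.95 0.95 0.90 0.90 0.80 0.95 0.80 0.95 0.90 0.95
```

`report$predictions` holds one out-of-fold row per sample (`p_lstm`,
`p_svm`, fused `p_final`, predicted label); `report$roc` the pooled ROC
points. Mean ACC 0.905 means 90.5% of held-out samples were classified
correctly on average across folds; AUC 0.956 is the probability that a
random case receives a higher fused score than a random control.

A command-line wrapper over the same functions ships in
`inst/scripts/pgpm.R` with subcommands `simulate`, `select`, `train`,
`evaluate` (see `--help`-style comments at the top of the file).

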