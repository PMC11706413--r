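---
title: "Methods: consensus feature selection and the LSTM-SVM hybrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus feature selection and the LSTM-SVM hybrid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pgpm` classifies subjects as Parkinson's disease (PD) cases or controls from
species-level gut-microbiome abundance profiles. This vignette documents the
statistical model, every tunable that matters, the numerical edge cases, and
what the synthetic benchmark does and does not demonstrate.

## Input model and assumptions

The input is a non-negative taxon × sample abundance matrix (relative
abundances or rounded pseudo-counts — the pipeline is agnostic, since its
first modelling step is rank- and variance-based and its second is min-max
normalization) plus one binary label per sample. Assumptions worth making
explicit:

* Abundances are comparable across samples; no additional compositional
  transform (CLR etc.) is applied. Closure effects are tolerated, not
  modelled.
* The cohort is roughly class-balanced (the motivating design is 39 cases
  and 39 spouse controls). Stratified fold assignment protects against
  degenerate folds, but severe imbalance would invalidate the accuracy
  metric before it broke the code.
* Samples are independent. Spousal pairing can optionally be respected in
  fold assignment (`kfold_split(..., pairs =)`), but the default ignores it,
  matching the original protocol's silence.

## Stage 1: CRFS consensus selection

Two rankings of all taxa are computed on training data:

* **Random forest importance** — mean decrease in Gini impurity across a
  500-tree classification forest, normalized to sum to 1. 500 trees is the
  conventional default for stable importance on a few hundred features; the
  count is configurable and a seed is mandatory.
* **PCA contribution** — the decomposition is computed on centred,
  *unscaled* data because normalization is deliberately ordered *after*
  selection in this pipeline; the per-taxon statistic is
  `contrib(j) = Σₘ evrₘ · loading(j, m)²` over the components retained, in
  decreasing eigenvalue order, until the cumulative explained-variance ratio
  reaches `variance_kept = 0.95`. "Contribution" has no single canonical
  definition; explained-variance-weighted squared loadings is the standard
  choice in the PCA literature and makes all contributions sum to the
  retained variance fraction, which gives a clean invariant to test. The
  statistic is unsupervised — labels never enter it.

The selected set is the intersection of the two top-`k` lists (`k = 20`),
ordered by RF rank. Ties within a ranking are broken lexicographically by
taxon name so the selection is deterministic. An empty intersection is an
error instructing the caller to raise `k` — the downstream model is undefined
on zero features. The selected columns are then min-max normalized; a
constant feature maps to all zeros (it carries no signal, and this avoids
0/0).

**Leakage control.** The original protocol selects features once on the full
dataset and then cross-validates; that lets the test folds influence feature
choice. The default here (`paper_mode = FALSE`) re-runs CRFS inside every
training fold. `paper_mode = TRUE` restores the original behaviour for
comparison. The toggle moves only *where* selection happens, never the model
equations — a property the test suite checks by comparing folds whose
selections coincide.

## Stage 2: the LSIM hybrid

**Sequence construction.** The method feeds a tabular feature vector to an
LSTM without an inherent time axis. We use a single time step (T = 1): the
whole selected-taxa vector is the input at t = 1 from the zero initial state,
and the "penultimate layer" is the final hidden state h₁. This is the
simplest faithful reading; per-feature time steps would be an equally
defensible alternative, but it multiplies training cost without a scientific
rationale on unordered taxa. A consequence worth knowing: with c₀ = 0 the
forget gate multiplies zero, so its weights receive no gradient — the gate is
computed but cannot influence a T = 1 model.

**Cell equations.** Standard LSTM: gates f, i, o are logistic sigmoids of
affine maps of `[x_t; h_{t-1}]`, the candidate context uses tanh, the
cell state is `c_t = f ⊙ c_{t-1} + i ⊙ c̃`, and `h_t = o ⊙ tanh(c_t)` (both
squashing functions taken as tanh, the standard choice). Every entry of
`h_t` therefore lies in [−1, 1], which bounds the SVM's input space.

**Training.** Cross-entropy on a 2-class softmax head, Adam with the
canonical constants (β₁ = 0.9, β₂ = 0.999, ε = 1e−8), learning rate 0.001,
batch size 6, 300 epochs, samples reshuffled every epoch. Weights initialize
uniformly in ±1/√H with a mandatory seed; biases at zero. Hidden size
defaults to H = 32: with ~70 training samples per fold in the motivating
design, a larger recurrent layer invites overfitting and a smaller one
under-parameterizes the penultimate representation. Gradients are analytic
(hand-derived for the single-step architecture) and verified against central
finite differences in the test suite; no autodiff framework is involved.

**SVM.** A soft-margin RBF SVM (cost C = 1, conventional default) is fit on
the penultimate vectors with the variance-scaled bandwidth
`γ = 1/(n_features · Var(X))`, where `Var(X)` pools all matrix entries —
the familiar "scale" heuristic, which makes γ invariant to feature count and
adapts it to the data's spread (scaling inputs by s scales γ by 1/s²).
Probabilities come from a Platt sigmoid fit on decision values from a seeded
3-fold internal cross-validation (in-sample when a class has fewer than 3
members), with Platt's smoothed targets `(N₊+1)/(N₊+2)` and `1/(N₋+2)` so
separable folds cannot blow up the fit. We do not use the solver library's
built-in probability mode because its internal shuffling is not seedable
from R and would break the pipeline's determinism contract. Prediction
evaluates the kernel expansion `Σᵢ αᵢyᵢK(sᵢ, x) + b` directly from stored
support vectors, so a fitted model serializes to plain JSON and the kernel
in use is exactly the package's `rbf_kernel`.

## Stage 3: soft voting and evaluation

The fused probability is the weighted mean of the LSTM softmax and
calibrated SVM probabilities, equal weights by default — these are the only
two probability sources in the architecture. The decision rule is
`p_final ≥ τ` with τ = 0.5; the boundary goes to the positive class.
Degenerate weights (1, 0) and (0, 1) reproduce the single voters exactly,
which the tests assert.

Evaluation is stratified k-fold cross-validation (k = 10). Each fold is held
out once as the test set; normalization ranges are learned on the training
fold and applied to the test fold with clipping to [0, 1], so a test value
outside the training range cannot leave the model's input domain. Reported:
per-fold accuracy, their mean, and the AUC of the pooled out-of-fold fused
scores. The ROC is a descending threshold sweep over unique scores (ties
collapse to one step), starting at (0, 0) and ending at (1, 1); AUC is the
trapezoid area, which equals the Mann–Whitney probability with ties counted
one half — the test suite checks this equivalence against a brute-force
pairwise oracle. TPR is TP/(TP+FN) and FPR is FP/(FP+TN); an undefined rate
(empty denominator) is returned as `NA`, never silently as 0.

Determinism: the master seed drives fold assignment and per-fold seeds for
the forest, the LSTM and the SVM calibration, so a re-run with the same
configuration reproduces every prediction bit for bit.

## The synthetic cohort generator

`generate_cohort()` emulates the *product* of an upstream taxonomic profiler
on a case/control design: log-normal baseline abundances
(`base_log_mean = 0`, `base_log_sd = 1` — a moderate, realistic spread of
roughly e^±2 across taxa), structural zeros placed uniformly at rate
`sparsity = 0.3` (a typical species-level detection gap; zeros are placed
*before* closure, mimicking undetected taxa in profiler output), optional
closure to per-sample relative abundances (on by default), and
`n_informative` planted taxa whose log-mean is shifted by `effect_logfold`
in cases. `default_study_spec()` mirrors the motivating design: 39 + 39
samples, 200 taxa, 8 informative taxa — the size of the consensus feature
set the original cohort yielded — at a unit log-fold effect.

What the generator does **not** emulate: phylogenetic correlation between
taxa, overdispersed counts (it is continuous, not count-based),
heterogeneous baseline abundances across taxa, batch effects, or
covariate structure (age, BMI, medication). Passing the synthetic benchmark
therefore shows the pipeline recovers planted monotone mean shifts at
realistic sparsity — it does not certify performance on real cohorts, where
effects are weaker, correlated and confounded.

## Benchmark problem sizes

The packaged benchmark scales the study design to 100 cases / 100 controls
with a 1.5 log-fold effect and trains 100 epochs per fold under 10-fold CV;
the acceptance script adds a label-permutation null on the same data. These
sizes give stable estimates (the null AUC's standard error at n = 200 is
about 0.04) while keeping a full run in tens of seconds. Smaller property
tests use 40–60 samples per arm, 5 folds and 40 epochs. At the original
39 + 39 scale with a unit effect the task is genuinely hard and
cross-validated accuracy is far below the benchmark's — an honest
consequence of n, not a defect; the benchmark's planted effect is
deliberately stronger so that failures indicate implementation regressions
rather than sampling noise.

## Known limitations

* The single-step LSTM cannot exploit any ordering of taxa; it acts as a
  bounded nonlinear feature map. Whether the original architecture unrolled
  over features is unrecoverable from its description.
* Platt calibration on ~180 decision values is coarse; fused probabilities
  near τ should not be over-interpreted.
* The consensus rule is a hard intersection: informative taxa invisible to
  *either* ranking (e.g. depleted taxa contribute little raw-scale variance
  and can be missed by unscaled PCA) are dropped. This is a property of the
  method being implemented, preserved deliberately.
* Accuracy is reported per fold and averaged; with 7–8 test samples per fold
  at the original scale, individual fold accuracies are quantized in steps
  of ~0.13.
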