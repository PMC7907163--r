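---
title: "Connectivity fingerprinting with dual-task neural network classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity fingerprinting with dual-task neural network classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis this package implements

`fcfingerprint` implements a task-based functional-connectivity
fingerprinting pipeline for reading skill. The scientific question is
whether the pattern of statistical couplings among regions of a
task-defined reading network carries a stable signature ("fingerprint") of
a child's reading-skill group (poor vs. highly-skilled), over and above the
signature of the stimulus class being read (word vs. pseudoword), and
whether that group signature persists when the same children perform an
unrelated task.

The pipeline has five stages:

1. **Featurization.** Each run's residualized ROI time series (115 ROIs in
   the reference design) is split in half, and two connectivity estimates
   are computed per half: the Pearson correlation and the cross-mutual
   information (XMI) of every ROI pair. The strictly-upper triangle of each
   115 × 115 matrix is vectorized (6,555 values), min-max rescaled to
   [0, 1], square-root transformed, and the 253 within-cluster pairs are
   masked out, leaving 6,302 features per pattern. Each run therefore
   yields four labelled patterns (2 halves × 2 estimators) — split-half
   augmentation that multiplies the training set while decorrelating the
   two estimator views (their patterns correlate positively but well below
   1).

2. **Dual-head classifier.** A multilayer perceptron maps each pattern to
   two simultaneous binary decisions: reading-skill group and lexicality.
   During training the input passes through Gaussian noise (SD 0.05) and
   dropout (rate 0.2); then three dense/batch-norm/ReLU hidden layers whose
   sizes follow `h1 = max(16, 2 * ceil(log2 i))`, `h2 = h3 = h1 / 2`; then
   two parallel single-unit sigmoid heads. The first dense layer carries an
   L1 penalty (0.0005). Training is plain SGD: learning rate 0.01 with
   inverse-time decay 0.05 per epoch, momentum 0.9, batch 16, at most 216
   epochs, early stopping on the validation lexicality-head loss with
   patience 16 and best-weight restoration, under stratified 5-fold
   cross-validation at the pattern level.

3. **Attribution and decimation.** A feature's influence on a head is its
   summed path weight — the sum over all hidden-unit paths of the product
   of dense weights, computed as `W1 W2 W3 w_head`. After each generation's
   folds are trained, per-head absolute path weights are summed across
   folds, and the union of the two heads' bottom deciles is removed.
   Generations repeat until at most `floor(0.05 × 6555) = 327` features
   remain; an additional evaluation generation is then trained on the final
   set without decimating. Twenty independent families repeat the whole
   loop from different seeds.

4. **Composite model.** Features appearing in at least 4 of 20 family
   final sets are pooled into a composite feature set and cross-validated
   with 10 folds. Mean signed path weights across folds are z-scored across
   features within each head; features with |Z| > 1 are flagged as highly
   relevant, their sign assigning the predicted class (negative →
   pseudoword / poor reader; positive → word / highly-skilled reader).
   Per-class adjacency matrices place each flagged edge's mean connectivity
   (over patterns of the predicted class) into an otherwise empty network
   for visualization.

5. **Transfer.** First-generation models trained on random stratified 0.66
   subsamples of the training-task patterns (5 sets × 3 partitions) are
   evaluated on every pattern of a different task performed by unseen
   participants. Group metrics are computed against the transfer group
   labels; the lexicality head, which has no ground truth there, is
   profiled as class proportions.

Performance is reported throughout with signal-detection and association
metrics: accuracy, d′ = z(hit rate) − z(false-alarm rate), the phi
coefficient of the 2 × 2 contingency table, and a one-degree-of-freedom
chi-squared test against the 50/50 chance split.

## The synthetic cohort generator

Raw imaging data are not required: `generate_cohort()` emulates the study
design at the ROI-time-series level so every downstream stage is testable.

* **Design.** 14 + 14 participants, 8 runs each (4 word, 4 pseudoword) of
  180 volumes at TR = 2 s (6 min; TR is fixed at a typical pediatric fMRI
  value so half a run is 90 samples). A transfer cohort (default 5 + 5
  participants, 4 runs) shares the group structure under a fresh task.
* **Generative model.** Each run is a stationary zero-mean multivariate
  normal draw from a group/condition-specific correlation matrix, plus a
  linear drift with random per-ROI slopes and two shared nuisance signals
  (a slow sinusoid and a standardized random walk) with random per-ROI
  loadings, both scaled by `nuisance_amplitude` (default 0.5 relative to
  the unit-variance neural signal). Event-related structure, HRF
  convolution and motion are deliberately not simulated: the analysis
  operates on whole-run residual series, and residualization against
  intercept + trend + nuisance regressors removes exactly the nuisance
  components the generator injects.
* **Planted effects.** The shared base correlation matrix holds
  within-cluster couplings at 0.5 (the packaged assignment has ten
  multi-ROI clusters — sizes 10, 10, 10, 10, 9, 6, 5, 4, 3, 3 — giving
  exactly 253 within-cluster pairs among 115 ROIs) and a predominantly
  positive random background (15% of between-cluster pairs drawn uniformly
  from [−0.10, 0.30]) — empirical BOLD connectivity is mostly positive and
  positively skewed, which is also what makes the Pearson- and XMI-derived
  views of the same half-run positively but not perfectly correlated. The
  background strength trades off two protocol-level phenomena that share
  one mechanism: stronger shared structure raises the cross-estimator
  pattern correlation, but it also lets a memorizing classifier match a
  validation pattern to its same-half sibling in the training set, which
  would push a null cohort's lexicality accuracy above chance. The default
  keeps the null cohort inside the binomial chance band while the
  cross-estimator correlation stays positive. Forty
  between-cluster edges carry a group effect (+0.3 for skilled readers) and
  forty disjoint edges carry a lexicality effect (+0.15 for words). The
  disjoint default mirrors the finding that group- and lexicality-
  predictive connections barely overlap, and decorrelates the two
  decimation rankings. The transfer cohort inherits the group edges and
  deltas but draws a fresh, disjoint task-edge set.
* **PSD repair.** Planting increments can leave the matrix indefinite. The
  repair alternates projections between the PSD cone (eigenvalue clipping
  at 1e-6, rescale to unit diagonal) and the set of matrices holding the
  planted cells at their target values, so planted couplings survive the
  repair essentially unchanged (within 0.02) rather than being silently
  shrunk — the planted delta is the condition being simulated, so it must
  actually be delivered. Off-diagonals are clipped to [−0.99, 0.99];
  the constrained repair converges comfortably for the default planted
  edge sets on the default background.
* **Individual fingerprints.** `participant_jitter_sd` can add a
  condition-stable idiosyncratic perturbation of the between-cluster
  couplings per participant. It defaults to 0: with pattern-level
  cross-validation folds a strong individual signature would let the group
  head succeed by participant recognition even with no group effect, which
  would defeat the null-cohort calibration check below. The knob exists
  because real cohorts do carry such signatures; enabling it makes the
  pattern-level protocol optimistic relative to participant-level folds,
  which is exactly the leakage the `group_by_participant` discussion in the
  field concerns.
* **One timepoint.** The archival datasets are longitudinal; whether both
  timepoints contributed classifier patterns is ambiguous, so the
  simulator emits a single timepoint per participant and tags runs with a
  `timepoint` field.

What the generator does **not** emulate — event-related dynamics,
non-stationarity, spatially structured physiological noise, scanner drift
families, or realistic inter-regional lag structure — bounds what passing
tests show: they validate the pipeline's statistical machinery and its
sensitivity/specificity under a known ground truth, not its behavior on
raw BOLD data.

## Numerical and design choices

* **Normalization order.** "Normalized and rescaled to [0, 1]" is
  implemented as a per-pattern min-max rescale (a preceding z-score is
  affinely absorbed by min-max), applied per method within each pattern,
  followed by the square root; [0, 1] is closed under both steps, rank
  order is preserved, and per-pattern scope cannot leak information across
  the train/validation split.
* **XMI estimator.** Zero-lag plug-in mutual information in bits over
  equal-frequency (quantile) bins, B = 8 per margin. It is rank-invariant
  (so invariant to monotone transforms), bounded by log2 B, and
  analytically checkable: a strictly monotone pair attains exactly
  log2 8 = 3 bits when T is a multiple of 8, and the independent-pair bias
  is approximately (B−1)²/(2T ln 2). A lag option exists but defaults to
  off. Degenerate columns (too few distinct values to fill the bins) are
  hard errors, as are zero-variance columns for the Pearson estimate.
* **Split convention.** Odd-length runs put the extra sample in the second
  half (`floor(T/2)` rows in the first).
* **Learning-rate decay.** "decay = 0.05" is read as inverse-time decay per
  epoch, `lr_t = 0.01 / (1 + 0.05 t)` — the conventional meaning of a
  `decay` argument for plain SGD.
* **Batch normalization.** Placed between the dense affine map and the
  ReLU; eps 1e-3. The running-statistics momentum is 0.9 rather than the
  common 0.99: with batch 16 and runs of only tens of epochs, a 0.99
  horizon leaves the inference statistics lagging the rapidly changing
  weights, which makes validation scores oscillate wildly from epoch to
  epoch; 0.9 matches the statistics horizon to the actual training length.
* **Early stopping.** Patience 16 epochs on the validation lexicality-head
  loss, with best-weight restoration (running statistics restored along
  with the weights). Ties at probability exactly 0.5 classify as 1.
* **Attribution.** Biases and batch-norm parameters are excluded from path
  products ("the matrices encoding the weights between each layer" are the
  dense weights). Fold aggregation sums absolute per-fold path weights per
  head before decimation; the composite z-scores mean signed weights
  (average-then-z rather than z-then-average). Bottom-decile cardinality is
  `ceil(0.1 F)` with ties broken toward the smaller feature index.
* **Stopping threshold and generation counting.** "0.05 of its original
  size" is anchored to the full 6,555-feature set (not the 6,302 post-mask
  set): the composite arithmetic (327 = 0.049 of the full set) implies it.
  The family trains one generation per feature set: each decimating cycle
  trains and then removes features, and once the retained count falls to
  ≤ 327 one last generation is trained on that final set without
  decimating — these final-generation models, with ~5% of the inputs, are
  the ones the composite analysis consumes, so they count as a trained
  generation. `n_generations` is therefore the number of decimating cycles
  plus one. Under the 10–20% per-cycle removal implied by the union rule,
  the decimating-cycle count is mathematically forced into [14, 29];
  nearly-disjoint head rankings land it at the bottom of that band, giving
  15–16 trained generations.
* **Trainable-weight ratio.** Direct evaluation of the layer-size rule
  gives final-generation models ≈ 0.04 of the first generation's dense
  weights (163,852 + heads vs. ≈ 6,200), not 0.01; the package reports the
  realized ratio via `count_dense_weights()` and asserts nothing about
  0.01.
* **d′ at ceiling.** Extreme rates are replaced by `1/(2n)` and
  `1 − 1/(2n)` for the relevant margin, so near-ceiling performance yields
  finite d′. Family-level 95% CIs use the t distribution. The chi-squared
  test is uncorrected. For the lexicality head, "word" is the signal class;
  for the group head, "highly-skilled".
* **Transfer partitions.** The 0.66 "folds" are independent stratified
  random subsamples, not a partition; the held-out 34% drives early
  stopping. Transfer patterns carry the lexicality label `transfer`, and
  supervised metric code refuses to score them — only class proportions
  are reported for that head.
* **Serialization.** Cohorts are TSV runs + a JSON sidecar; pattern sets
  are TSV matrices + a JSON manifest; models are a single JSON container at
  full double precision. Every container carries a schema version and
  loading a mismatched version is an explicit error.
* **Seeds.** Every stage derives its seed as a 31-bit hash of the global
  seed and a stage tag (`derive_seed`), so no stage consumes another's
  stream and any stage can be reproduced in isolation.

## Problem sizes used by the packaged checks

The reference experiment (115 ROIs, 14 + 14 participants, 896 patterns ×
6,302 features) is used where the check concerns the reference dynamics:
the decimation generation count (one family, epochs capped at 64 with early
stopping, ≈ 6–10 min on one CPU) and the first-generation calibration and
null-cohort calibration (5 folds at the default 216-epoch budget). Checks
of distributional behavior — planted-edge recovery across families,
composite enrichment, transfer — use reduced cohorts (20–40 ROIs, 6–16
participants, shorter epoch budgets) chosen so the whole suite runs in
tens of minutes on one CPU; the thresholds applied to those checks are not
relaxed relative to the full-scale statements. Each test names its sizes
inline.

## Known limitations

* The stationary-Gaussian generator cannot produce genuinely nonlinear
  dependencies, so XMI never carries information Pearson misses here; on
  real data the two estimators are complementary rather than redundant.
* With `participant_jitter_sd = 0` every run of a group/condition cell is
  exchangeable, making pattern-level and participant-level folds
  equivalent in expectation; with jitter enabled the pattern-level
  protocol is optimistic, as discussed above.
* The decimation loop retrains the architecture from scratch each
  generation; nothing is warm-started, so compute grows linearly with the
  number of generations and families.
* The composite reliability threshold (4 of 20) is meaningful because it
  pins the composite near 5% of the full feature set; for other family
  counts use `tune_min_family_count()` rather than carrying 4 over.
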