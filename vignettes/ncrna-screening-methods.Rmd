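---
title: "Methods: stability-selected noncoding RNA panels and neural-network cancer screening"
author: "ncscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability-selected noncoding RNA panels and neural-network cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncscreen)
```

# The problem

Population-level cancer screening from transcript abundance asks two
questions in sequence: *is this sample cancerous at all* (a binary decision
against a small number of healthy controls), and if so, *which of the common
cancer types is it* (a multiclass decision across ~26 types). Noncoding RNAs
are attractive markers for both because a small, fixed panel can be assayed
cheaply. ncscreen implements the full analysis path: ranking candidate
markers by stability selection on TPM expression matrices, training
fixed-architecture feed-forward networks on accumulated panels, and deciding
how many markers are *enough* via a Kruskal-Wallis turning-point criterion
over independently resampled training sets.

Everything operates on raw TPM (transcripts per million) values. No
model-based normalisation, filtering or outlier removal is applied anywhere
in the pipeline — robustness to raw real-world inputs is part of what the
evaluation measures. An optional `log1p` input transform exists on the model
side for experimentation and is off by default.

# Data model and splits

Cohorts are samples-by-features matrices of non-negative TPM values with a
class label per sample (`"normal"` or a cancer type). `split_samples()`
performs a sequential random partition: the test set takes
$\lceil 0.2\,N \rceil$ samples, the validation set
$\lceil 0.2\,(N - n_{test}) \rceil$ of the remainder, and the rest trains.
The ceiling convention is deliberate: it is the single rounding rule under
which a 9057-sample cohort yields exactly 1812 / 1449 / 5796, the sizes the
reference compendium reports. Splits are sample-wise uniform; stratification
by class is available (`stratify = TRUE`) but off by default, since the
protocol being reproduced splits without stratification despite ~13:1
cancer:normal imbalance.

# The synthetic cohort generator

Real cohorts of this kind cannot ship with a package, so `generate_cohort()`
draws cohorts from an explicit generative law and records ground truth:

* **Background**: each entry is log-normal,
  $x_{ij} = \exp(\mu_0 + \sigma_0 Z)$, with defaults $\mu_0 = 1.5$,
  $\sigma_0 = 1.2$. Log-normality was chosen because TPM is non-negative and
  heavy-tailed; the defaults put the median background transcript near
  4.5 TPM with a long right tail reaching the hundreds, which is typical for
  noncoding RNAs (lowly expressed, occasionally high).
* **Dropout**: each entry is independently forced to exactly 0 with
  probability 0.3, emulating transcripts unexpressed or unmeasured in a
  sample. Thirty percent zeros is a realistic order for noncoding RNA rows
  of bulk TPM tables.
* **Planted signal**: `n_informative` features are each assigned one target
  cancer class, round-robin, so every cancer class receives markers whenever
  `n_informative >= n_classes`; in its target class a marker's log-mean is
  shifted by `effect_size`. An effect of 3 on the natural-log scale
  (~20-fold) models a strongly dysregulated marker; 1.0 a moderate one.
* **Imbalance**: the default configuration mirrors the reference compendium
  (632 normal vs 8425 cancer over 26 types, ~13:1), though all tests and
  examples use far smaller configurations.

`generate_paired_external_cohort()` draws an independent cohort from the
same law with two deliberate distortions: only a chosen fraction of the
feature identifiers match the primary cohort (the rest are renamed,
emulating annotation mismatch between data sources), and the log-scale
standard deviation is inflated by a fixed factor of 1.5, emulating the
extra variation and outliers of independently collected validation data.
The factor is a documented constant, not a fitted quantity.

What the generator does **not** emulate: read-level sequencing noise, batch
effects, correlated marker modules, survival outcomes, or any specific
biology of exosome (blood) measurements beyond low identifier overlap and
higher variance. Tests passing on these cohorts demonstrate that the
machinery recovers planted structure under realistic marginals and
imbalance — not that any particular biological panel is valid.

# Stability selection

`select_stable_features()` implements resampling stability selection. Each
of $n$ iterations randomly partitions the samples into $m$ disjoint,
equal-size ($\pm 1$) subgroups ($m = 2$, $n = 100$ by default, the lower
ends of the protocol's stated ranges). On every subgroup a sparse linear
classifier is fitted and the features with nonzero coefficients recorded.
Over the $m \times n$ runs each feature accumulates a selection count; its
**frequency score** is count / completed runs, and the ranked panel (ties
broken by ascending feature identifier, so ranking is total and
deterministic) is the object all downstream stages consume. Features whose
score reaches the consistency threshold (default 1.0 — selected in *every*
run, the strict reading of "consistently selected") form the flagged final
set.

Design choices a maintainer should know:

* **Base selector.** An L1-penalised logistic regression (glmnet), fitted
  one-vs-rest across the classes present in a subgroup; the selected set is
  the union of the per-class supports. The protocol names only a sparse
  SVM-embedded selector without loss or penalty details; L1-logistic is the
  standard sparse linear choice in the R ecosystem and the selector is a
  single pluggable function. Supports are read off the regularisation path
  at a fixed `regularization_strength` (default $\lambda = 0.1$ on
  internally standardised features, a mid-path value that keeps a handful
  of features per run on cohorts of the sizes used here); as
  $\lambda \to \infty$ the selection is empty.
* **Degenerate subgroups.** A subgroup with fewer than two classes holding
  at least two samples each cannot support a fit; such runs are skipped and
  excluded from the frequency-score denominator. Excluding rather than
  counting them avoids biasing scores downward for rare-class cohorts.
* **Multiclass pooling.** Per-class supports are pooled (union) into one
  score per feature rather than kept per class; the panel is consumed as a
  single ranking downstream.
* **Independent resamples.** `rank_for_multiclass()` repeats the whole
  procedure on 8 (configurable) independently drawn training sets — each
  with its own test/validation/training split whose validation and test
  samples never touch selection — producing one ranked panel per resample.
  Run-to-run agreement of these panels is exactly what the turning-point
  analysis later interrogates.

# The neural networks

Two fixed architectures, written in base R matrix arithmetic and trained by
mini-batch Adam on cross-entropy:

| task | dense stack | head |
|---|---|---|
| binary (cancer vs normal) | 30 units, 60 units | 1 sigmoid unit |
| multiclass (26-way) | six layers of 240 units | softmax over classes |

Every dense layer except the output is followed by relu and dropout at rate
0.1 (inverted dropout, so prediction needs no rescaling). Training runs
exactly 30 epochs at batch size 20 with per-epoch shuffling and **no early
stopping**; the loss/accuracy history for training and validation is
recorded every epoch and is the object from which convergence statements
are read. The output heads and losses (sigmoid + binary cross-entropy;
softmax + categorical cross-entropy) are the standard pairing for the
accuracy and AUC metrics reported; the protocol leaves them unstated. Adam
runs at its conventional defaults (learning rate 0.001,
$\beta_1 = 0.9$, $\beta_2 = 0.999$); weights are Glorot-uniform
initialised. Everything — initialisation, shuffling, dropout masks — draws
from one seeded stream, so a fixed seed reproduces histories and
predictions exactly, and the global RNG state of the caller is never
disturbed.

Feeding raw TPM into a dense network is unusual but intentional (the
protocol does exactly that); Adam's per-parameter step normalisation is
what makes the wide dynamic range of raw TPM workable. If training ever
produces a non-finite loss the fit aborts with a diagnostic suggesting the
`log1p` transform flag. Class weighting is available
(`class_weight = TRUE`) but off by default, matching the protocol's
unweighted training despite imbalance.

Baselines (`fit_baseline()`) are a random forest and a single decision
tree at their standard library defaults (rpart's internal cross-validation
is disabled so tree fits are deterministic), wrapped behind the same
`predict_scores()` contract so `compare_models()` can treat all three
kinds identically on identical splits.

# Evaluation

**AUC** is defined as the Mann-Whitney concordance
$P(s^+ > s^-) + \tfrac12 P(s^+ = s^-)$ computed from mid-ranks; the
threshold-sweep ROC curve and its trapezoidal area are the independent
cross-check (they agree to $10^{-12}$ in the tests, and brute-force pair
counting is a second oracle).

**Kruskal-Wallis** is computed on mid-ranks with the standard tie
correction and a $\chi^2_{k-1}$ p-value. All-identical observations give
$H = 0$, $p = 1$ by definition rather than an error — this matters because
the turning-point scan begins in a regime where runs can be exactly tied.
The chi-square approximation is the usual choice for the group sizes used
here (tests confirm a null type-I error near nominal at
3 groups x 10 observations).

**Accumulation curves** retrain a fresh model at every panel size
$k = 1..K$ on the top-$k$ markers and record the test metric (AUC for
binary, accuracy for multiclass) plus final train/validation losses. Each
size gets a seed derived from the curve seed, so curves are reproducible
yet sizes are not trained on identical shuffles.

**Turning point.** With 8 resampled runs there is one accuracy per run at
each panel size, and a per-size Kruskal-Wallis across runs would be
degenerate on singleton groups. The minimal well-defined reading — and the
package's documented choice — is a trailing window: at size $k$ each run
contributes its accuracies at sizes $k - w + 1, \dots, k$ (default
$w = 10$), and the scan records $p(k)$. The turning point $k^\*$ is the
largest $k$ with $p(j) \ge \alpha$ for every testable $j \le k$ (default
$\alpha = 0.1$): the last size before sustained run-to-run divergence, at
which accuracy is taken to be independent of training-set sampling. If runs
already differ at the first testable size the result is flagged "not
found". Both $\alpha$ and $w$ are configuration, because the protocol pins
neither the grouping nor the exact crossing convention.

# Pipeline and reproducibility

`run_pipeline()` chains load → split → selection per resample →
accumulation curves → turning point → final model on the top-$k^\*$
markers, writing each stage's artifact (panel TSVs, curve CSVs, p-trace
CSV, JSON summary) plus a `run.log` holding the master seed, every derived
stage seed, input md5 checksums and stage parameters — enough to reproduce
the run. One master seed derives all stage seeds by hashing stage labels
(`derive_seed()`), so any stage can be reproduced in isolation. Reruns
with the same configuration are byte-identical.

`validate_external()` mirrors external validation: the panel is
intersected with the features the external cohort measures (missing
markers are dropped, never zero-imputed), the binary network is retrained
on the matched subset using the internal training samples, and AUC is
computed on the raw external values. Retraining on the intersected subset
is an interpretation — the protocol does not say whether its external
tests retrained or padded inputs — and is flagged as such here. Matched
panels under 10 markers are flagged `low_overlap`; very small panels were
observed to validate unstably.

# Numerical conventions

* Expression TSVs print 17 significant digits so doubles round-trip
  bit-exactly; reading applies no transformation and rejects negative or
  non-numeric cells naming the line and column.
* Panel ranking ties break by ascending feature identifier everywhere, so
  every ranking is total and reproducible.
* All seeds are 32-bit-safe; `derive_seed()` maps (master seed, stage
  label) into $[1, 2^{31}-2]$.
* Degenerate inputs are errors with named causes (empty split sets, zero
  marker overlap, single-class AUC), except where a definition is the
  natural continuation ($H = 0, p = 1$ for all-tied Kruskal-Wallis).

# Problem sizes used by the tests and acceptance script

The package's own verification runs at desk scale, chosen so the full
suite completes in about a minute: the planted-marker cohort is 150
samples (normal + two cancer classes, 50 each) x 200 features with 10
markers at log-effect 3; stability selection runs m = 2, n = 100; the
no-signal control uses a 600-sample, 50-feature cohort so the null AUC of
a 120-sample test set concentrates tightly enough for a meaningful
[0.35, 0.65] band; pipeline determinism runs 2 resamples at K = 12.
Full-scale study conditions (9057 samples, K = 300, 8 resamples) are
reachable with the same functions and the default generator configuration.

# Known limitations

* The Kruskal-Wallis comparison across the three model kinds (and, at
  full scale, across accumulation traces generally) treats per-size
  metrics as independent draws. Accumulated panels are nested and share
  one split, so within-trace autocorrelation makes that test
  anticonservative; its p-values should be read as descriptive. The
  turning-point scan is less exposed (it compares runs built from
  *independent* resamples) but the same caveat applies to its windowed
  groups.
* The band checks on no-signal cohorts are stochastic assertions with
  high but not total coverage; a decision tree's tied scores make its
  null AUC the most granular of the three model kinds.
* The generator's independent log-normal features cannot represent
  correlated marker modules; stability selection's behaviour under strong
  feature correlation (known to split frequency scores between correlated
  partners) is therefore not exercised.
* The networks are trained for a fixed 30 epochs with no architecture or
  hyperparameter search, by design; nothing here should be read as a
  tuned-performance claim.
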