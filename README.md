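# ncscreen

Noncoding RNA biomarker panels for multi-cancer screening: stability-selected
marker ranking, fixed-architecture neural-network classifiers, and a
Kruskal–Wallis turning-point criterion for deciding how many markers a panel
needs.

## What it does

Screening cancers from TPM (transcripts-per-million) expression matrices
proceeds in two stages: a binary cancer-vs-normal decision, then a multiclass
call across cancer types. `ncscreen` implements the full analysis path as a
tested R package:

* **Stability selection** (`select_stable_features`): samples are partitioned
  into *m* disjoint subgroups per iteration, *n* iterations; an L1-penalised
  one-vs-rest logistic fit selects features in each of the *m·n* runs; every
  feature is ranked by its **frequency score** — the fraction of runs that
  selected it — with the features selected in every run flagged as the final
  set. `rank_for_multiclass` repeats this on 8 independently resampled
  training sets.
* **Classifiers** (`fit_nn`): feed-forward networks trained with mini-batch
  Adam on cross-entropy for a fixed 30 epochs, batch size 20, dropout 0.1
  after every hidden layer — a 30/60-unit stack with a sigmoid head for the
  binary screen, six 240-unit layers with a softmax head for the multiclass
  panel. Raw TPM goes in; no normalisation is applied anywhere.
  `fit_baseline` wraps random forest and decision tree behind the same
  scoring contract for comparison (`compare_models`).
* **Evaluation** (`auc`, `roc_curve`, `kruskal_wallis`,
  `accumulation_curve`): AUC as Mann–Whitney concordance
  P(s⁺ > s⁻) + ½ P(s⁺ = s⁻); tie-corrected Kruskal–Wallis H with a χ²
  p-value; accumulation curves retraining a fresh model on the top-k markers
  for k = 1..K.
* **Turning point** (`turning_point`): across resampled runs, the largest
  panel size k\* at which the runs' accuracies remain statistically
  indistinguishable (windowed Kruskal–Wallis p ≥ α, default α = 0.1) — the
  panel size past which accuracy becomes dependent on training-set sampling.
* **Synthetic cohorts** (`generate_cohort`): log-normal TPM with dropout and
  planted class-specific markers, plus paired "external" cohorts sharing only
  a fraction of feature identifiers at inflated variance, so every stage is
  testable offline. `run_pipeline` chains everything from TSV inputs to a
  JSON summary with full seed/checksum logging; `validate_external` evaluates
  a panel on an external cohort after marker intersection
  (`intersect_markers`).

## Worked example

```r
library(ncscreen)

# a 150-sample cohort: 50 normal, two cancer types of 50, with 10 planted
# markers among 200 noncoding RNAs
cfg <- synthetic_config(n_classes = 2, samples_per_class = c(50, 50, 50),
                        n_features = 200, n_informative = 10,
                        effect_size = 3, seed = 7)
cohort <- generate_cohort(cfg)

# rank markers by stability selection (m = 2 subgroups x n = 100 iterations)
sel <- select_stable_features(cohort$expression, cohort$labels,
                              stability_params(m = 2, n = 100, seed = 7))
sel
#> Stability selection: 200 completed runs (m=2 x n=100, 0 skipped)
#>   182 features ever selected; 2 in final set at threshold 1
head(sel$panel, 5)
#>    feature_id frequency_score rank selected
#> 1 ncRNA_00006           1.000    1     TRUE
#> 2 ncRNA_00007           1.000    2     TRUE
#> 3 ncRNA_00005           0.990    3    FALSE
#> 4 ncRNA_00004           0.985    4    FALSE
#> 5 ncRNA_00010           0.965    5    FALSE

# train the binary screening network on the top 10 markers
split <- split_samples(nrow(cohort$expression), 0.2, 0.2, seed = 7)
y <- binarize_labels(cohort$labels)
feats <- sel$panel$feature_id[1:10]
fit <- fit_nn(cohort$expression[split$train, feats], y[split$train],
              nn_config("binary", seed = 7),
              val_x = cohort$expression[split$val, feats],
              val_y = y[split$val])
fit
#> Cancer-screening NN (binary): 10 features -> [30, 60] -> sigmoid, 2251 parameters
#>   final epoch 30: loss 0.7767, accuracy 0.7604 (validation loss 1.1266, accuracy 0.7500)

# held-out test AUC
auc(predict(fit, cohort$expression[split$test, feats]), y[split$test])
#> [1] 0.9473684
```

The top of the ranked panel is dominated by planted markers (`ncRNA_00001`
to `ncRNA_00010` carry the simulated signal), and ten stability-selected
markers screen cancer from normal on held-out samples with AUC ≈ 0.95.

The methods vignette (`vignettes/ncrna-screening-methods.Rmd`) documents the
generative model, the selector, the network training contract, the
turning-point definition and the package's numerical conventions.

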