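# Shared fixtures and independent oracles. Expensive objects (cohorts,
# stability-selection runs) are computed once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# planted-marker study fixture: 2 cancer classes + normal, 200 features,
# 10 informative at log-effect 3
planted_config <- function(seed = 7) {
  synthetic_config(n_classes = 2, samples_per_class = c(50, 50, 50),
                   n_features = 200, n_informative = 10, effect_size = 3,
                   seed = seed)
}

planted_cohort <- function(seed = 7) {
  cached(paste0("planted", seed), generate_cohort(planted_config(seed)))
}

planted_selection <- function(seed = 7, n = 100) {
  cached(paste0("sel", seed, "_", n), {
    co <- planted_cohort(seed)
    select_stable_features(co$expression, co$labels,
                           stability_params(m = 2, n = n, seed = seed))
  })
}

# pure-noise version of the same fixture
noise_cohort <- function(seed = 11) {
  cfg <- planted_config(seed)
  cfg$effect_size <- 0
  cached(paste0("noise", seed), generate_cohort(cfg))
}

# small binary cohort (one cancer class) for quick model tests
small_binary_cohort <- function(seed = 1, effect_size = 3, n_features = 20,
                                n_per_class = 60, n_informative = 5) {
  generate_cohort(synthetic_config(
    n_classes = 1, samples_per_class = c(n_per_class, n_per_class),
    n_features = n_features, n_informative = n_informative,
    effect_size = effect_size, seed = seed))
}

# independent oracle: AUC by brute force over all positive/negative pairs,
# ties counted one half
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# independent oracle: rank the features of a cohort by per-feature
# Kruskal-Wallis rank-sum p-value across the class labels (brute-force
# univariate screening; markers planted in one cancer class shift only that
# class, so the across-class test is the right univariate probe)
rank_sum_screening <- function(expression, labels) {
  p <- apply(expression, 2L, function(v) {
    stats::kruskal.test(split(v, labels))$p.value
  })
  names(sort(p))
}

# small on-disk cohort + pipeline configuration shared by the pipeline and
# determinism tests
pipeline_fixture_dir <- function() {
  cached("pipe_fixture_dir", {
    co <- generate_cohort(synthetic_config(
      n_classes = 2, samples_per_class = c(50, 50, 50), n_features = 60,
      n_informative = 8, effect_size = 3, seed = 17))
    d <- file.path(tempdir(), "ncscreen-pipe-fixture")
    write_fixture(co$expression, co$labels, co$truth, d)
    d
  })
}

small_pipeline_config <- function(out_dir, seed = 42) {
  d <- pipeline_fixture_dir()
  pipeline_config(
    expression = file.path(d, "expression.tsv"),
    labels = file.path(d, "labels.tsv"),
    task = "binary",
    stability = stability_params(m = 2, n = 5, seed = 1),
    K = 12, window = 10, n_resamples = 2, seed = seed, out_dir = out_dir)
}

# constructed accumulation traces: identical through k = k_split, then
# run-specific offsets (the turning-point worked example)
constructed_curves <- function(n_runs = 8, K = 100, k_split = 50,
                               base = 0.8, step = 0.01) {
  lapply(seq_len(n_runs), function(run) {
    metric <- c(rep(base, k_split),
                rep(base + step * run, K - k_split))
    structure(data.frame(k = seq_len(K), metric = metric,
                         train_loss = NA_real_, val_loss = NA_real_),
              class = c("accumulation_curve", "data.frame"),
              metric_name = "accuracy", model_kind = "constructed")
  })
}
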