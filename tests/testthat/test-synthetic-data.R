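# Synthetic cohort generator: structure, determinism, planted signal.

test_that("generated cohorts have the configured shape and invariants", {
  cfg <- synthetic_config(n_classes = 2, samples_per_class = c(30, 20, 25),
                          n_features = 40, n_informative = 6,
                          effect_size = 2, seed = 3)
  co <- generate_cohort(cfg)
  expect_identical(dim(co$expression), c(75L, 40L))
  expect_true(all(co$expression >= 0))
  expect_true(all(is.finite(co$expression)))
  expect_identical(as.vector(table(factor(co$labels,
                                          c("normal", "cancer01", "cancer02")))),
                   c(30L, 20L, 25L))
  # planted markers assigned round-robin over the cancer classes
  expect_identical(co$truth$feature_id, colnames(co$expression)[1:6])
  expect_identical(co$truth$target_class,
                   rep(c("cancer01", "cancer02"), 3))
  # no marker targets the normal class
  expect_false("normal" %in% co$truth$target_class)
})

test_that("cohorts are deterministic per seed and differ across seeds", {
  cfg <- synthetic_config(n_classes = 1, samples_per_class = c(10, 10),
                          n_features = 15, n_informative = 2,
                          effect_size = 1, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- cfg
  cfg2$seed <- 6L
  expect_false(identical(generate_cohort(cfg2)$expression, a$expression))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_classes = 2, samples_per_class = c(5, 5)),
               "length")
  expect_error(synthetic_config(n_classes = 1, samples_per_class = c(5, 0),
                                n_features = 10),
               "at least one sample")
  expect_error(synthetic_config(n_features = 5, n_informative = 6),
               "exceed")
  expect_error(synthetic_config(dropout_rate = 1.2), "dropout_rate")
})

test_that("zero informative features yield an empty ground truth", {
  co <- generate_cohort(synthetic_config(
    n_classes = 1, samples_per_class = c(8, 8), n_features = 10,
    n_informative = 0, effect_size = 5, seed = 1))
  expect_identical(nrow(co$truth), 0L)
})

test_that("with zero effect size informative features are exchangeable across classes", {
  # rank-sum p-values over repeated seeds should look uniform
  pvals <- vapply(1:20, function(s) {
    co <- generate_cohort(synthetic_config(
      n_classes = 1, samples_per_class = c(25, 25), n_features = 3,
      n_informative = 1, effect_size = 0, seed = s))
    v <- co$expression[, 1L]
    stats::wilcox.test(v[co$labels == "normal"],
                       v[co$labels != "normal"], exact = FALSE)$p.value
  }, 0)
  # p-values from the normal-approximation rank-sum test are mildly
  # discrete, so ties can occur; the KS check is still a fair uniformity probe
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("downstream classifier AUC is non-decreasing in effect size", {
  mean_auc <- vapply(c(0, 1, 3), function(es) {
    mean(vapply(1:5, function(s) {
      co <- small_binary_cohort(seed = s, effect_size = es)
      sp <- split_samples(nrow(co$expression), 0.2, 0.2, seed = s)
      y <- binarize_labels(co$labels)
      fit <- fit_nn(co$expression[sp$train, ], y[sp$train],
                    nn_config("binary", seed = s))
      auc(predict(fit, co$expression[sp$test, ]), y[sp$test])
    }, 0))
  }, 0)
  expect_true(all(diff(mean_auc) >= 0))
})

test_that("external cohort shares exactly the requested identifier fraction", {
  cfg <- synthetic_config(n_classes = 1, samples_per_class = c(10, 10),
                          n_features = 56, n_informative = 4,
                          effect_size = 1, seed = 2)
  primary <- generate_cohort(cfg)
  full <- generate_paired_external_cohort(cfg, shared_fraction = 1)
  expect_setequal(colnames(full$expression), colnames(primary$expression))
  part <- generate_paired_external_cohort(cfg, shared_fraction = 39 / 56,
                                          id_mangle_seed = 4)
  expect_identical(
    sum(colnames(part$expression) %in% colnames(primary$expression)), 39L)
  expect_error(generate_paired_external_cohort(cfg, shared_fraction = 0),
               "shared_fraction")
})

test_that("external cohort is drawn with inflated log-scale dispersion", {
  cfg <- synthetic_config(n_classes = 1, samples_per_class = c(100, 100),
                          n_features = 50, n_informative = 0,
                          effect_size = 0, dropout_rate = 0, seed = 9)
  primary <- generate_cohort(cfg)
  ext <- generate_paired_external_cohort(cfg, shared_fraction = 1)
  ratio <- stats::sd(log(ext$expression)) / stats::sd(log(primary$expression))
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 1.7)
})

test_that("fixtures round-trip exactly through the TSV formats", {
  co <- generate_cohort(synthetic_config(
    n_classes = 2, samples_per_class = c(50, 50, 50), n_features = 12,
    n_informative = 3, effect_size = 2, seed = 8))
  d <- withr::local_tempdir()
  paths <- write_fixture(co$expression, co$labels, co$truth, d)
  back <- read_expression_matrix(paths[["expression"]])
  expect_identical(back, co$expression)
  labs <- read_labels(paths[["labels"]])
  expect_identical(unname(labs), co$labels)
  expect_identical(names(labs), rownames(co$expression))
  expect_identical(read_marker_truth(paths[["truth"]]), co$truth)
  # 150 samples -> header + 150 lines
  expect_identical(length(readLines(paths[["expression"]])), 151L)
  # byte-identical across repeated writes of the same cohort
  d2 <- withr::local_tempdir()
  paths2 <- write_fixture(co$expression, co$labels, co$truth, d2)
  expect_identical(readLines(paths2[["expression"]]),
                   readLines(paths[["expression"]]))
  expect_error(write_fixture(co$expression[0, , drop = FALSE],
                             character(0), NULL, d),
               "0 samples")
})
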