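# ROC/AUC, Kruskal-Wallis, accumulation curves, turning point, comparison.

test_that("auc matches hand-checked concordance examples", {
  expect_identical(auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1)
  # 3 of 4 pairs concordant
  expect_identical(auc(c(0.8, 0.3, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_identical(auc(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("auc equals brute-force pairwise concordance, ties included", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(6:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    # discrete score support forces ties
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(auc(s, y), brute_force_auc(s, y), tolerance = 1e-14)
  }
})

test_that("auc is invariant under monotone transforms and flips under negation", {
  set.seed(7)
  s <- rexp(40)
  y <- rbinom(40, 1, 0.4)
  a <- auc(s, y)
  expect_equal(auc(log1p(s), y), a, tolerance = 1e-12)
  expect_equal(auc(s^3, y), a, tolerance = 1e-12)
  expect_equal(auc(-s, y), 1 - a, tolerance = 1e-12)  # s has no ties a.s.
})

test_that("roc curves are valid and their trapezoid area equals the rank auc", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
  set.seed(55)
  for (i in 1:20) {
    n <- sample(10:100, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)
    curve <- roc_curve(s, y)
    expect_identical(curve$fpr[1], 0)
    expect_identical(curve$tpr[1], 0)
    expect_identical(curve$fpr[nrow(curve)], 1)
    expect_identical(curve$tpr[nrow(curve)], 1)
    expect_true(!is.unsorted(curve$fpr) && !is.unsorted(curve$tpr))
    expect_equal(attr(curve, "auc"), auc(s, y), tolerance = 1e-12)
  }
  set.seed(56)
  rnd <- roc_curve(runif(1000), rbinom(1000, 1, 0.5))
  expect_gt(attr(rnd, "auc"), 0.45)
  expect_lt(attr(rnd, "auc"), 0.55)
})

test_that("kruskal_wallis reproduces the hand-computed 3x3 example", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(res$statistic, 7.2, tolerance = 1e-12)
  expect_identical(res$df, 2L)
  same <- kruskal_wallis(list(1:3, 1:3, 1:3))
  expect_identical(same$statistic, 0)
  expect_identical(same$p.value, 1)
})

test_that("kruskal_wallis agrees with the reference implementation", {
  set.seed(202)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(g) {
      round(stats::rnorm(sample(3:12, 1)), sample(0:2, 1))  # induce ties
    })
    mine <- kruskal_wallis(groups)
    ref <- stats::kruskal.test(groups)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-9)
  }
  expect_error(kruskal_wallis(list(1:3)), ">= 2")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), ">= 1 observation")
})

test_that("accumulated markers improve the test metric on a planted fixture", {
  co <- generate_cohort(synthetic_config(
    n_classes = 1, samples_per_class = c(60, 60), n_features = 30,
    n_informative = 5, effect_size = 3, seed = 13))
  # rank planted markers first, then noise
  feats <- colnames(co$expression)
  panel <- marker_panel(feats, seq(1, 0.5, length.out = length(feats)))
  sp <- split_samples(120, 0.2, 0.2, seed = 13)
  y <- binarize_labels(co$labels)
  cu <- accumulation_curve(panel, co$expression, y, sp, "nn", K = 8, seed = 13)
  expect_identical(cu$k, 1:8)
  expect_identical(attr(cu, "metric_name"), "auc")
  expect_gte(cu$metric[8], cu$metric[1])
  expect_true(all(is.finite(cu$train_loss)))
  single <- accumulation_curve(panel, co$expression, y, sp, "nn", K = 1,
                               seed = 13)
  expect_identical(nrow(single), 1L)
  expect_error(accumulation_curve(panel, co$expression, y, sp, K = 31),
               "exceeds")
})

test_that("turning point locates the onset of run-to-run divergence", {
  curves <- constructed_curves(n_runs = 8, K = 100, k_split = 50)
  tp <- turning_point(curves, alpha = 0.1, window = 10)
  expect_true(tp$found)
  expect_gte(tp$k_star, 50)
  expect_lt(tp$k_star, 60)
  testable <- tp$p_trace$p[10:50]
  expect_true(all(testable == 1))
  # past the split, run r sits at 0.8 + 0.01 r, so the cross-run mean is
  # 0.8 + 0.01 * mean(1:8) whatever k* in [51, 60) the window lands on
  expect_equal(tp$mean_metric_at_k_star, 0.8 + 0.01 * mean(1:8),
               tolerance = 1e-12)
})

test_that("identical runs never diverge; mismatched grids are rejected", {
  one <- constructed_curves(n_runs = 1, K = 40, k_split = 40)[[1]]
  tp <- turning_point(list(one, one, one), alpha = 0.1, window = 5)
  expect_true(tp$found)
  expect_identical(tp$k_star, 40L)
  short <- constructed_curves(n_runs = 1, K = 20, k_split = 20)[[1]]
  expect_error(turning_point(list(one, short)), "same marker-count grid")
  expect_error(turning_point(list(one)), ">= 2")
})

test_that("turning point is monotone in alpha", {
  set.seed(77)
  noisy <- lapply(1:6, function(run) {
    m <- c(rep(0.8, 30), rep(0.8, 30) + 0.002 * run) + rnorm(60, 0, 0.004)
    structure(data.frame(k = 1:60, metric = m, train_loss = NA_real_,
                         val_loss = NA_real_),
              class = c("accumulation_curve", "data.frame"))
  })
  alphas <- c(0.01, 0.1, 0.5)
  kstars <- vapply(alphas, function(a) {
    tp <- turning_point(noisy, alpha = a, window = 10)
    if (tp$found) tp$k_star else 0L
  }, 0L)
  expect_true(all(diff(kstars) <= 0))
})

test_that("model comparison runs all three kinds on identical splits", {
  co <- generate_cohort(synthetic_config(
    n_classes = 1, samples_per_class = c(100, 100), n_features = 25,
    n_informative = 5, effect_size = 3, seed = 14))
  feats <- colnames(co$expression)
  panel <- marker_panel(feats, seq(1, 0.5, length.out = length(feats)))
  sp <- split_samples(200, 0.2, 0.2, seed = 14)
  y <- binarize_labels(co$labels)
  cm <- compare_models(panel, co$expression, y, sp, K = 6, seed = 14)
  expect_named(cm$curves, c("nn", "random_forest", "decision_tree"))
  expect_length(cm$curves, 3)
  # strong planted signal: every model kind separates well at its best k
  for (cu in cm$curves) expect_gte(max(cu$metric), 0.9)
  expect_true(is.finite(cm$kw$p.value))
})
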