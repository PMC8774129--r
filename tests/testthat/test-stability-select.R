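# Stability selection: base selector, run accounting, frequency ranking.

test_that("a perfectly separating feature is selected by the base learner", {
  # feature 1 separates the classes with a wide margin; the rest are noise
  set.seed(42)
  n <- 40
  y <- rep(c("normal", "cancer01"), each = n / 2)
  x <- matrix(rexp(n * 10), nrow = n,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:10)))
  x[, 1] <- ifelse(y == "cancer01", 10, 1) + runif(n, 0, 0.5)
  # oracle: exhaustively check single-feature separability
  separable <- vapply(seq_len(ncol(x)), function(j) {
    max(x[y == "normal", j]) < min(x[y == "cancer01", j]) ||
      max(x[y == "cancer01", j]) < min(x[y == "normal", j])
  }, TRUE)
  expect_identical(which(separable), 1L)
  sel <- base_select(x, y, stability_params(regularization_strength = 0.2))
  expect_true("f01" %in% sel)
})

test_that("degenerate subgroups are skipped, extreme penalties select nothing", {
  x <- matrix(rexp(60), nrow = 12,
              dimnames = list(sprintf("s%02d", 1:12), sprintf("f%d", 1:5)))
  expect_null(base_select(x, rep("normal", 12), stability_params()))
  y <- rep(c("normal", "cancer01"), each = 6)
  sel <- base_select(x, y, stability_params(regularization_strength = 1e6))
  expect_identical(sel, character(0))
})

test_that("run accounting: completed + skipped = m * n, scores within [0, 1]", {
  # one class has only 3 samples, so many random subgroups are degenerate
  co <- generate_cohort(synthetic_config(
    n_classes = 1, samples_per_class = c(27, 3), n_features = 20,
    n_informative = 2, effect_size = 3, seed = 4))
  sel <- select_stable_features(co$expression, co$labels,
                                stability_params(m = 3, n = 10, seed = 4))
  expect_identical(sel$total_runs + sel$skipped_runs, 30L)
  expect_gt(sel$skipped_runs, 0L)
  expect_true(all(sel$panel$frequency_score >= 0 &
                    sel$panel$frequency_score <= 1))
  expect_true(all(sel$counts >= 0 & sel$counts <= sel$total_runs))
})

test_that("stability selection recovers planted markers in the top ranks", {
  co <- planted_cohort(7)
  sel <- planted_selection(7)
  top10 <- sel$panel$feature_id[1:10]
  expect_gte(sum(top10 %in% co$truth$feature_id), 8)
  # independent oracle: per-feature rank-sum screening agrees the signal is
  # recoverable from the fixture
  oracle_top10 <- rank_sum_screening(co$expression, co$labels)[1:10]
  expect_gte(sum(oracle_top10 %in% co$truth$feature_id), 8)
})

test_that("strongly consistent features reach frequency score 1", {
  co <- generate_cohort(synthetic_config(
    n_classes = 1, samples_per_class = c(40, 40), n_features = 30,
    n_informative = 1, effect_size = 5, seed = 3))
  scores <- vapply(1:3, function(s) {
    sel <- select_stable_features(co$expression, co$labels,
                                  stability_params(m = 2, n = 10, seed = s))
    sel$panel$frequency_score[match(co$truth$feature_id,
                                    sel$panel$feature_id)]
  }, 0)
  expect_true(all(scores == 1))
})

test_that("the final set shrinks monotonically in the consistency threshold", {
  co <- planted_cohort(7)
  sel <- planted_selection(7)
  sets <- lapply(c(0.5, 0.8, 1.0), function(th) {
    sel$panel$feature_id[sel$panel$frequency_score >= th]
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
  # and the selected flag matches the threshold rule
  expect_setequal(sel$panel$feature_id[sel$panel$selected], sets[[3]])
})

test_that("selection is deterministic per seed", {
  co <- generate_cohort(synthetic_config(
    n_classes = 1, samples_per_class = c(20, 20), n_features = 25,
    n_informative = 2, effect_size = 2, seed = 6))
  a <- select_stable_features(co$expression, co$labels,
                              stability_params(m = 2, n = 5, seed = 9))
  b <- select_stable_features(co$expression, co$labels,
                              stability_params(m = 2, n = 5, seed = 9))
  expect_identical(a$counts, b$counts)
  expect_identical(a$panel, b$panel)
})

test_that("multiclass resampling returns one sorted panel per resample", {
  co <- generate_cohort(synthetic_config(
    n_classes = 2, samples_per_class = c(30, 30, 30), n_features = 40,
    n_informative = 6, effect_size = 3, seed = 5))
  panels <- rank_for_multiclass(co$expression, factor(co$labels),
                                stability_params(m = 2, n = 2, seed = 5),
                                n_resamples = 8)
  expect_length(panels, 8)
  for (p in panels) {
    expect_s3_class(p, "marker_panel")
    expect_false(is.unsorted(rev(p$frequency_score)))
    expect_s3_class(attr(p, "split"), "data_split")
  }
  # a single resample equals a direct call with the same derived seed
  one <- rank_for_multiclass(co$expression, factor(co$labels),
                             stability_params(m = 2, n = 2, seed = 5),
                             n_resamples = 1)[[1]]
  seed1 <- derive_seed(5, "resample1")
  split1 <- split_samples(90, 0.2, 0.2, seed = seed1)
  direct <- select_stable_features(
    co$expression[split1$train, ], co$labels[split1$train],
    stability_params(m = 2, n = 2, seed = seed1))
  expect_identical(one$feature_id, direct$panel$feature_id)
  expect_identical(one$frequency_score, direct$panel$frequency_score)
})

test_that("panels agree across resamples more under signal than under noise", {
  jaccard_top <- function(panels, k = 20) {
    tops <- lapply(panels, function(p) p$feature_id[seq_len(min(k, nrow(p)))])
    pairs <- utils::combn(length(tops), 2)
    mean(apply(pairs, 2, function(ij) {
      a <- tops[[ij[1]]]; b <- tops[[ij[2]]]
      length(intersect(a, b)) / length(union(a, b))
    }))
  }
  mk <- function(effect) {
    co <- generate_cohort(synthetic_config(
      n_classes = 1, samples_per_class = c(40, 40), n_features = 60,
      n_informative = 10, effect_size = effect, seed = 12))
    rank_for_multiclass(co$expression, binarize_labels(co$labels),
                        stability_params(m = 2, n = 5, seed = 12),
                        n_resamples = 4)
  }
  expect_gt(jaccard_top(mk(3)), jaccard_top(mk(0)))
})
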