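# Resampling stability selection with frequency-score ranking.
#
# Each iteration partitions the samples into m disjoint, equal-size (+/- 1)
# subgroups; a sparsity-inducing linear classifier is fitted to every
# subgroup and the features with nonzero coefficients are recorded. Over n
# iterations this yields m*n runs; a feature's frequency score is the
# fraction of completed runs that selected it, and the "final" biomarker set
# is the features whose score reaches the consistency threshold (default 1:
# selected in every run).

#' Parameters for stability selection
#'
#' @param m number of disjoint subgroups per iteration (>= 2).
#' @param n number of iterations (the study works with n >= 100).
#' @param consistency_threshold fraction of completed runs in which a
#'   feature must be selected to enter the final biomarker set, in (0, 1].
#'   The default 1 is the strict reading of "consistently selected".
#' @param base_selector sparse base learner; currently `"l1-logistic"`, an
#'   L1-penalised logistic regression fitted one-vs-rest across classes
#'   (the union of per-class supports is the selected set).
#' @param regularization_strength penalty strength (the glmnet `lambda` at
#'   which supports are read off; features are standardised internally by
#'   the fit, so the scale is comparable across features). Larger values
#'   give sparser selections; as it grows without bound the selected set
#'   becomes empty.
#' @param seed integer seed; the whole procedure is deterministic per seed.
#' @return an object of class `stability_params`.
#' @export
stability_params <- function(m = 2L, n = 100L, consistency_threshold = 1,
                             base_selector = "l1-logistic",
                             regularization_strength = 0.1, seed = 1) {
  check_scalar(m, "m", integer = TRUE, lower = 2)
  check_scalar(n, "n", integer = TRUE, lower = 1)
  check_scalar(consistency_threshold, "consistency_threshold",
               lower = 1e-12, upper = 1)
  base_selector <- match.arg(base_selector, "l1-logistic")
  check_scalar(regularization_strength, "regularization_strength", lower = 1e-12)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(m = as.integer(m), n = as.integer(n),
         consistency_threshold = consistency_threshold,
         base_selector = base_selector,
         regularization_strength = regularization_strength,
         seed = as.integer(seed)),
    class = "stability_params"
  )
}

#' Sparse base selection on one subgroup
#'
#' Fits the configured L1-penalised linear classifier one-vs-rest across
#' the classes present in the subgroup and returns the feature identifiers
#' with nonzero coefficients (union over classes). Subgroups with fewer
#' than two usable classes (a class needs at least two samples to
#' participate) yield `NULL`, which callers treat as a skipped run.
#'
#' @param x subgroup expression matrix (samples x features).
#' @param y class labels aligned to rows.
#' @param params a [stability_params()].
#' @return character vector of selected feature identifiers, or `NULL` for
#'   a degenerate (effectively single-class) subgroup.
#' @export
base_select <- function(x, y, params = stability_params()) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.character(y)
  tab <- table(y)
  usable <- names(tab)[tab >= 2L]
  if (length(usable) < 2L) return(NULL)
  classes <- if (length(usable) == 2L) usable[2L] else usable
  support <- character(0)
  for (cls in classes) {
    yb <- as.integer(y == cls)
    # small subgroups are the point of the resampling scheme; silence
    # glmnet's small-class advisory but let anything else through
    fit <- withCallingHandlers(
      glmnet::glmnet(x, yb, family = "binomial", alpha = 1,
                     standardize = TRUE),
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    co <- stats::coef(fit, s = params$regularization_strength)
    nz <- rownames(co)[as.vector(co != 0)]
    support <- union(support, setdiff(nz, "(Intercept)"))
  }
  sort(support)
}

#' Stability selection over m subgroups and n iterations
#'
#' Runs [base_select()] on every subgroup of every iteration, accumulates
#' per-feature selection counts, and ranks all ever-selected features by
#' frequency score (count / completed runs; ties broken by ascending
#' feature identifier). Features at or above the consistency threshold are
#' flagged as the final biomarker set. Degenerate subgroups (fewer than two
#' usable classes) are skipped and excluded from the denominator so that
#' frequency scores are not biased downward.
#'
#' @param x expression matrix (samples x features, feature colnames).
#' @param y class labels aligned to rows.
#' @param params a [stability_params()].
#' @return an object of class `stability_selection` with components
#'   `panel` (a [marker_panel()] with a `selected` flag), `counts` (named
#'   integer vector over all features), `total_runs`, `skipped_runs`, and
#'   `params`.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(
#'   n_classes = 1, samples_per_class = c(25, 25), n_features = 40,
#'   n_informative = 3, effect_size = 3, seed = 2))
#' sel <- select_stable_features(cohort$expression, cohort$labels,
#'                               stability_params(m = 2, n = 5, seed = 2))
#' head(sel$panel, 3)
select_stable_features <- function(x, y, params = stability_params()) {
  check_expression_matrix(x)
  stopifnot(nrow(x) == length(y))
  if (nrow(x) < 2L * params$m) {
    stop("need at least 2 samples per subgroup (", 2L * params$m,
         " total for m = ", params$m, ")", call. = FALSE)
  }
  n_samples <- nrow(x)
  counts <- stats::setNames(integer(ncol(x)), colnames(x))
  completed <- 0L
  skipped <- 0L
  with_seed(params$seed, {
    for (iter in seq_len(params$n)) {
      # disjoint, equal-size (+/- 1) subgroups by random assignment
      grp <- sample(rep(seq_len(params$m), length.out = n_samples))
      for (g in seq_len(params$m)) {
        rows <- which(grp == g)
        feats <- base_select(x[rows, , drop = FALSE], y[rows], params)
        if (is.null(feats)) {
          skipped <- skipped + 1L
        } else {
          completed <- completed + 1L
          counts[feats] <- counts[feats] + 1L
        }
      }
    }
  })
  if (completed == 0L) {
    stop("no stability-selection run completed (all subgroups degenerate)",
         call. = FALSE)
  }
  ever <- counts > 0L
  freq <- counts[ever] / completed
  panel <- marker_panel(
    names(counts)[ever], freq,
    selected = freq >= params$consistency_threshold,
    provenance = sprintf(
      "stability selection: m=%d, n=%d, threshold=%.3g, selector=%s, lambda=%.3g, seed=%d",
      params$m, params$n, params$consistency_threshold, params$base_selector,
      params$regularization_strength, params$seed)
  )
  structure(
    list(panel = panel, counts = counts, total_runs = completed,
         skipped_runs = skipped, params = params),
    class = "stability_selection"
  )
}

#' @export
print.stability_selection <- function(x, ...) {
  cat(sprintf(
    "Stability selection: %d completed runs (m=%d x n=%d, %d skipped)\n",
    x$total_runs, x$params$m, x$params$n, x$skipped_runs))
  cat(sprintf("  %d features ever selected; %d in final set at threshold %.3g\n",
              nrow(x$panel), sum(x$panel$selected),
              x$params$consistency_threshold))
  invisible(x)
}

#' @export
summary.stability_selection <- function(object, ...) {
  print(object)
  cat("Top of the ranked panel:\n")
  print.data.frame(utils::head(as.data.frame(object$panel), 10L))
  invisible(object)
}

#' Ranked marker panels from independent training resamples
#'
#' Repeats the full procedure on independently drawn training sets: each
#' resample performs its own test/validation/training split (validation and
#' test samples are never used for selection) and runs
#' [select_stable_features()] on the training samples only. The study uses
#' eight independent resamples to probe how marker ranking depends on
#' training-set sampling.
#'
#' @param x full cohort expression matrix.
#' @param y class labels aligned to rows.
#' @param params a [stability_params()]; per-resample seeds are derived
#'   deterministically from `params$seed`.
#' @param n_resamples number of independent training resamples (default 8).
#' @param test_frac,val_frac split fractions passed to [split_samples()].
#' @return a list of [marker_panel()] objects, one per resample; each panel
#'   carries its `data_split` and derived seed as attributes `split` and
#'   `seed`.
#' @export
rank_for_multiclass <- function(x, y, params = stability_params(),
                                n_resamples = 8L,
                                test_frac = 0.2, val_frac = 0.2) {
  check_scalar(n_resamples, "n_resamples", integer = TRUE, lower = 1)
  lapply(seq_len(n_resamples), function(r) {
    seed_r <- derive_seed(params$seed, paste0("resample", r))
    split <- split_samples(nrow(x), test_frac, val_frac, seed = seed_r)
    pr <- params
    pr$seed <- seed_r
    sel <- select_stable_features(x[split$train, , drop = FALSE],
                                  y[split$train], pr)
    panel <- sel$panel
    attr(panel, "split") <- split
    attr(panel, "seed") <- seed_r
    panel
  })
}
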