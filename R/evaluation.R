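# Evaluation layer: ROC/AUC, accumulated-biomarker curves, the
# Kruskal-Wallis rank-sum statistic, the turning-point search that fixes a
# stable panel size, and the three-model comparison.

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) return(as.integer(labels == levels(labels)[2L]))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) {
      stop("numeric labels must be 0/1 (1 = positive)", call. = FALSE)
    }
    return(as.integer(labels))
  }
  stop("labels must be logical, 0/1 numeric, or a two-level factor ",
       "(second level = positive)", call. = FALSE)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance via mid-ranks: the probability
#' that a random positive sample outscores a random negative, counting ties
#' as one half. Identical (to numerical precision) to the trapezoidal area
#' under [roc_curve()].
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels: logical, 0/1, or a two-level factor whose
#'   second level is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))  # 1
#' auc(c(0.8, 0.3, 0.6, 0.2), c(1, 1, 0, 0))  # 0.75
auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y))
  if (any(!is.finite(scores))) stop("non-finite scores", call. = FALSE)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC needs both classes present (", n_pos, " positive, ", n_neg,
         " negative)", call. = FALSE)
  }
  r <- rank(scores)  # mid-ranks handle ties
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve from a threshold sweep
#'
#' One point per distinct score threshold plus the (0,0) and (1,1)
#' endpoints; both coordinates are non-decreasing and the trapezoidal area
#' equals [auc()].
#'
#' @inheritParams auc
#' @return a data.frame of class `roc_curve` with columns `fpr`, `tpr` and
#'   attribute `auc` (trapezoidal area).
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  last <- which(!duplicated(ss, fromLast = TRUE))  # last index per threshold
  tp <- cumsum(ys)[last]
  fp <- last - tp
  curve <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  area <- sum(diff(curve$fpr) * (curve$tpr[-1L] + curve$tpr[-nrow(curve)]) / 2)
  attr(curve, "auc") <- area
  class(curve) <- c("roc_curve", "data.frame")
  curve
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x), attr(x, "auc")))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "false-positive rate",
                 ylab = "true-positive rate",
                 main = sprintf("AUC = %.3f", attr(x, "auc")), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Kruskal-Wallis rank-sum test
#'
#' The H statistic on mid-ranks with the standard tie correction, with the
#' p-value from the chi-square approximation on `k - 1` degrees of freedom.
#' When every observation is identical the statistic is defined as 0 with
#' p = 1 (no evidence of difference), not an error.
#'
#' @param groups a list of two or more numeric vectors, each non-empty,
#'   with at least three observations in total.
#' @return a list with `statistic` (H), `p.value`, and `df`.
#' @export
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$statistic  # 7.2
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("'groups' must be a list of >= 2 numeric vectors", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group needs >= 1 observation", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  if (!is.numeric(pooled) || any(!is.finite(pooled))) {
    stop("groups must contain finite numeric values", call. = FALSE)
  }
  N <- length(pooled)
  if (N < 3L) stop("need >= 3 observations in total", call. = FALSE)
  k <- length(groups)
  r <- rank(pooled)
  grp <- rep(seq_len(k), times = sizes)
  rank_sums <- tapply(r, grp, sum)
  H <- 12 / (N * (N + 1)) * sum(rank_sums^2 / sizes) - 3 * (N + 1)
  ties <- table(pooled)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (correction <= 0) {
    # all observations identical
    return(list(statistic = 0, p.value = 1, df = k - 1L))
  }
  H <- H / correction
  list(statistic = H,
       p.value = stats::pchisq(H, df = k - 1L, lower.tail = FALSE),
       df = k - 1L)
}

#' Accumulated-biomarker performance curve
#'
#' For each panel size k = 1..K, trains a fresh model on the top-k ranked
#' markers using the training samples and records the test-set metric
#' (AUC for a binary task, accuracy for multiclass) together with the final
#' training and validation losses (neural network only).
#'
#' @param panel a [marker_panel()] ranking the candidate markers.
#' @param x full cohort expression matrix; must measure the panel features.
#' @param y class labels aligned to rows (two-level factor for binary; see
#'   [binarize_labels()]).
#' @param split a [split_samples()] result on `nrow(x)`.
#' @param model_kind `"nn"`, `"random_forest"` or `"decision_tree"`.
#' @param K largest panel size (`<=` panel length).
#' @param config optional [nn_config()] for the neural network.
#' @param seed integer seed; each panel size trains with a seed derived
#'   from it.
#' @return a data.frame of class `accumulation_curve` with columns `k`,
#'   `metric`, `train_loss`, `val_loss` and attributes `metric_name`,
#'   `model_kind`, `seed`.
#' @export
accumulation_curve <- function(panel, x, y, split, model_kind = "nn",
                               K = nrow(panel), config = NULL, seed = 1) {
  stopifnot(inherits(panel, "marker_panel"), inherits(split, "data_split"))
  model_kind <- match.arg(model_kind, c("nn", "random_forest", "decision_tree"))
  check_scalar(K, "K", integer = TRUE, lower = 1)
  if (K > nrow(panel)) {
    stop("K (", K, ") exceeds the panel length (", nrow(panel), ")",
         call. = FALSE)
  }
  missing <- setdiff(panel$feature_id[seq_len(K)], colnames(x))
  if (length(missing) > 0L) {
    stop("panel feature(s) not measured in the cohort: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  y <- as.factor(as.character(y))
  binary <- nlevels(y) == 2L
  metric_name <- if (binary) "auc" else "accuracy"
  out <- data.frame(k = seq_len(K), metric = NA_real_,
                    train_loss = NA_real_, val_loss = NA_real_)
  for (k in seq_len(K)) {
    feats <- panel$feature_id[seq_len(k)]
    xk <- x[, feats, drop = FALSE]
    seed_k <- derive_seed(seed, paste0("k", k))
    fit <- fit_screen_model(model_kind,
                            xk[split$train, , drop = FALSE], y[split$train],
                            config = config,
                            val_x = xk[split$val, , drop = FALSE],
                            val_y = y[split$val], seed = seed_k)
    probs <- predict_scores(fit, xk[split$test, , drop = FALSE])
    yt <- y[split$test]
    out$metric[k] <- if (binary) {
      auc(probs[, levels(y)[2L]], yt)
    } else {
      mean(colnames(probs)[max.col(probs)] == as.character(yt))
    }
    if (model_kind == "nn") {
      h <- fit$history[nrow(fit$history), ]
      out$train_loss[k] <- h$loss
      out$val_loss[k] <- h$val_loss
    }
  }
  attr(out, "metric_name") <- metric_name
  attr(out, "model_kind") <- model_kind
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat(sprintf("Accumulation curve (%s, %s): k = 1..%d, final %s = %.4f, max = %.4f\n",
              attr(x, "model_kind"), attr(x, "metric_name"), nrow(x),
              attr(x, "metric_name"), x$metric[nrow(x)], max(x$metric)))
  invisible(x)
}

#' @export
plot.accumulation_curve <- function(x, ...) {
  graphics::plot(x$k, x$metric, type = "l", xlab = "accumulated biomarkers",
                 ylab = attr(x, "metric_name"), ...)
  invisible(x)
}

#' Turning point of run-to-run accuracy divergence
#'
#' Given accumulation curves from independently resampled runs, tests at
#' each panel size k whether the runs' recent accuracies differ
#' (Kruskal-Wallis across runs, each run contributing its trailing
#' `window` values ending at k). The turning point `k_star` is the largest
#' k such that p >= alpha at every testable size up to k - the last panel
#' size before sustained run-to-run divergence, at which accuracy is taken
#' to be independent of training-set sampling.
#'
#' @param curves list of >= 2 [accumulation_curve()]s on the same k grid.
#' @param alpha significance cutoff (default 0.1, the study's cutoff).
#' @param window trailing window length per run (>= 2, default 10); a
#'   single accuracy per run would make the per-size test degenerate.
#' @return an object of class `turning_point` with `k_star`, `found`,
#'   `mean_metric_at_k_star`, `p_trace` (data.frame `k`, `p`), `alpha`,
#'   `window`.
#' @export
turning_point <- function(curves, alpha = 0.1, window = 10L) {
  if (!is.list(curves) || length(curves) < 2L) {
    stop("'curves' must be a list of >= 2 accumulation curves", call. = FALSE)
  }
  check_scalar(alpha, "alpha", lower = 1e-12, upper = 1)
  check_scalar(window, "window", integer = TRUE, lower = 2)
  ks <- curves[[1L]]$k
  for (cu in curves[-1L]) {
    if (!identical(cu$k, ks)) {
      stop("all curves must share the same marker-count grid", call. = FALSE)
    }
  }
  if (length(ks) < window) {
    stop("curves are shorter than the window (", window, ")", call. = FALSE)
  }
  p <- rep(NA_real_, length(ks))
  for (i in seq(window, length(ks))) {
    groups <- lapply(curves, function(cu) cu$metric[(i - window + 1L):i])
    p[i] <- kruskal_wallis(groups)$p.value
  }
  testable <- which(!is.na(p))
  fail <- testable[p[testable] < alpha]
  if (length(fail) == 0L) {
    k_star <- ks[length(ks)]
    found <- TRUE
  } else if (fail[1L] == testable[1L]) {
    k_star <- NA_integer_
    found <- FALSE
  } else {
    k_star <- ks[fail[1L] - 1L]
    found <- TRUE
  }
  mean_metric <- if (found) {
    mean(vapply(curves, function(cu) cu$metric[cu$k == k_star], 0))
  } else {
    NA_real_
  }
  structure(
    list(k_star = k_star, found = found,
         mean_metric_at_k_star = mean_metric,
         p_trace = data.frame(k = ks, p = p),
         alpha = alpha, window = as.integer(window),
         n_runs = length(curves)),
    class = "turning_point"
  )
}

#' @export
print.turning_point <- function(x, ...) {
  if (x$found) {
    cat(sprintf(
      "Turning point over %d runs (alpha = %.3g, window = %d): k* = %d\n",
      x$n_runs, x$alpha, x$window, x$k_star))
    cat(sprintf("  mean metric at k*: %.4f\n", x$mean_metric_at_k_star))
  } else {
    cat(sprintf(
      "No turning point found: runs already differ (p < %.3g) at the first testable size\n",
      x$alpha))
  }
  invisible(x)
}

#' Compare the neural network against baseline models
#'
#' Builds accumulation curves for the neural network, random forest and
#' decision tree on identical train/validation/test splits, and tests
#' whether the three models' metric traces differ (Kruskal-Wallis across
#' models over the k grid).
#'
#' @inheritParams accumulation_curve
#' @return an object of class `model_comparison`: list with `curves`
#'   (named list of three [accumulation_curve()]s) and `kw` (the
#'   Kruskal-Wallis result across models).
#' @export
compare_models <- function(panel, x, y, split, K = nrow(panel),
                           config = NULL, seed = 1) {
  kinds <- c("nn", "random_forest", "decision_tree")
  curves <- lapply(kinds, function(kind) {
    accumulation_curve(panel, x, y, split, model_kind = kind, K = K,
                       config = config, seed = derive_seed(seed, kind))
  })
  names(curves) <- kinds
  kw <- kruskal_wallis(lapply(curves, function(cu) cu$metric))
  structure(list(curves = curves, kw = kw), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison on identical splits:\n")
  for (nm in names(x$curves)) {
    cu <- x$curves[[nm]]
    cat(sprintf("  %-14s max %s = %.4f (at k = %d)\n", nm,
                attr(cu, "metric_name"), max(cu$metric),
                cu$k[which.max(cu$metric)]))
  }
  cat(sprintf("  Kruskal-Wallis across models: H = %.3f, p = %.3g\n",
              x$kw$statistic, x$kw$p.value))
  invisible(x)
}
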