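# End-to-end orchestration: load -> split -> (optional) stability selection
# -> accumulation curves per resample -> turning point -> final model, with
# a reproducibility log. A single master seed deterministically derives
# every stage seed, so stages are independently reproducible and a rerun
# with the same configuration is byte-identical for deterministic outputs.

#' Pipeline configuration
#'
#' Validates all referenced paths up front (before any compute) and
#' collects the stage parameters. When `panel` is `NULL` the pipeline runs
#' stability selection per resample; otherwise the given ranked panel file
#' is used for every run and only the splits differ between runs.
#'
#' @param expression path to the expression TSV.
#' @param labels path to the labels TSV.
#' @param panel optional path to a ranked marker-panel TSV.
#' @param task `"multiclass"` (all classes, accuracy metric) or
#'   `"binary"` (cancer vs normal, AUC metric).
#' @param stability a [stability_params()] (used when `panel` is `NULL`).
#' @param nn optional [nn_config()]; defaults to the task's standard
#'   architecture.
#' @param K largest accumulated panel size (study value 300; scale down
#'   for small cohorts).
#' @param alpha turning-point significance cutoff (default 0.1).
#' @param window turning-point trailing window (default 10).
#' @param n_resamples independent training resamples (study value 8).
#' @param test_frac,val_frac split fractions (default 0.2 and 0.2).
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory for artifacts.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, labels, panel = NULL,
                            task = c("multiclass", "binary"),
                            stability = stability_params(),
                            nn = NULL, K = 300L, alpha = 0.1, window = 10L,
                            n_resamples = 8L, test_frac = 0.2, val_frac = 0.2,
                            seed = 1, out_dir = tempfile("ncscreen_run_")) {
  task <- match.arg(task)
  for (p in c(expression, labels, panel)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  stopifnot(inherits(stability, "stability_params"))
  if (!is.null(nn)) stopifnot(inherits(nn, "nn_config"))
  check_scalar(K, "K", integer = TRUE, lower = 1)
  check_scalar(alpha, "alpha", lower = 1e-12, upper = 1)
  check_scalar(window, "window", integer = TRUE, lower = 2)
  if (window > K) {
    stop("turning-point window (", window, ") exceeds K (", K, ")",
         call. = FALSE)
  }
  check_scalar(n_resamples, "n_resamples", integer = TRUE, lower = 2)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(expression = expression, labels = labels, panel = panel,
         task = task, stability = stability, nn = nn, K = as.integer(K),
         alpha = alpha, window = as.integer(window),
         n_resamples = as.integer(n_resamples),
         test_frac = test_frac, val_frac = val_frac,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full screening pipeline
#'
#' Executes load, split, (optional) stability selection per resample,
#' accumulation curves per resample, the turning-point search, and a final
#' model trained on the top `k_star` markers, writing every stage's output
#' plus a reproducibility log (`run.log`: seeds, input checksums,
#' parameters) under `config$out_dir`. Deterministic artifacts are
#' byte-identical across reruns with the same configuration.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, an object of class `ncscreen_run` with the panels,
#'   curves, turning point, final model and final test metric.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  note("ncscreen pipeline: task=%s, K=%d, alpha=%g, window=%d, resamples=%d, master_seed=%d",
       config$task, config$K, config$alpha, config$window,
       config$n_resamples, config$seed)
  note("input expression: %s md5=%s", config$expression,
       unname(tools::md5sum(config$expression)))
  note("input labels: %s md5=%s", config$labels,
       unname(tools::md5sum(config$labels)))

  x <- read_expression_matrix(config$expression)
  lab <- read_labels(config$labels)
  if (!all(rownames(x) %in% names(lab))) {
    stop("labels file does not cover all samples in the expression matrix",
         call. = FALSE)
  }
  lab <- lab[rownames(x)]
  y <- if (config$task == "binary") binarize_labels(lab) else
    factor(as.character(lab))
  note("cohort: %d samples x %d features, %d classes", nrow(x), ncol(x),
       nlevels(y))

  # one panel + split per resample
  if (is.null(config$panel)) {
    sp <- config$stability
    sp$seed <- derive_seed(config$seed, "stability")
    panels <- rank_for_multiclass(x, y, sp, n_resamples = config$n_resamples,
                                  test_frac = config$test_frac,
                                  val_frac = config$val_frac)
    note("stability selection per resample: m=%d n=%d lambda=%g seed=%d",
         sp$m, sp$n, sp$regularization_strength, sp$seed)
  } else {
    base_panel <- read_marker_panel(config$panel)
    note("fixed panel: %s (%d markers) md5=%s", config$panel,
         nrow(base_panel), unname(tools::md5sum(config$panel)))
    panels <- lapply(seq_len(config$n_resamples), function(r) {
      seed_r <- derive_seed(config$seed, paste0("resample", r))
      p <- base_panel
      attr(p, "split") <- split_samples(nrow(x), config$test_frac,
                                        config$val_frac, seed = seed_r)
      attr(p, "seed") <- seed_r
      p
    })
  }
  for (r in seq_along(panels)) {
    write_marker_panel(panels[[r]],
                       file.path(config$out_dir, sprintf("panel_run%d.tsv", r)))
    note("resample %d: seed=%d, panel=%d markers", r,
         attr(panels[[r]], "seed"), nrow(panels[[r]]))
  }

  K <- min(config$K, min(vapply(panels, nrow, 0L)))
  if (K < config$K) {
    note("K reduced to %d (shortest ranked panel)", K)
  }
  if (K < config$window) {
    stop("ranked panels are shorter (", K, ") than the turning-point window (",
         config$window, ")", call. = FALSE)
  }
  curves <- lapply(seq_along(panels), function(r) {
    cu <- accumulation_curve(panels[[r]], x, y, attr(panels[[r]], "split"),
                             model_kind = "nn", K = K, config = config$nn,
                             seed = derive_seed(config$seed, paste0("curve", r)))
    utils::write.csv(as.data.frame(cu),
                     file.path(config$out_dir, sprintf("curve_run%d.csv", r)),
                     row.names = FALSE)
    cu
  })

  tp <- turning_point(curves, alpha = config$alpha, window = config$window)
  utils::write.csv(tp$p_trace, file.path(config$out_dir, "p_trace.csv"),
                   row.names = FALSE)
  k_star <- if (tp$found) tp$k_star else K
  note("turning point: found=%s k_star=%s mean_metric=%s", tp$found,
       as.character(tp$k_star), format(tp$mean_metric_at_k_star, digits = 6))

  # final model on the top-k_star markers of the first resample
  final_panel <- panels[[1L]]
  final_split <- attr(final_panel, "split")
  feats <- final_panel$feature_id[seq_len(k_star)]
  final_seed <- derive_seed(config$seed, "final-model")
  final_fit <- fit_screen_model("nn", x[final_split$train, feats, drop = FALSE],
                                y[final_split$train], config = config$nn,
                                val_x = x[final_split$val, feats, drop = FALSE],
                                val_y = y[final_split$val], seed = final_seed)
  probs <- predict_scores(final_fit, x[final_split$test, feats, drop = FALSE])
  final_metric <- if (nlevels(y) == 2L) {
    auc(probs[, levels(y)[2L]], y[final_split$test])
  } else {
    mean(colnames(probs)[max.col(probs)] == as.character(y[final_split$test]))
  }
  metric_name <- if (nlevels(y) == 2L) "auc" else "accuracy"
  note("final model: k_star=%d seed=%d test_%s=%.6f", k_star, final_seed,
       metric_name, final_metric)

  summary <- list(task = config$task, n_samples = nrow(x),
                  n_features = ncol(x), K = K, alpha = config$alpha,
                  window = config$window, n_resamples = config$n_resamples,
                  k_star = k_star, turning_point_found = tp$found,
                  mean_metric_at_k_star = tp$mean_metric_at_k_star,
                  final_test_metric = final_metric,
                  metric_name = metric_name, master_seed = config$seed)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))

  invisible(structure(
    list(config = config, panels = panels, curves = curves,
         turning_point = tp, k_star = k_star, final_model = final_fit,
         final_test_metric = final_metric, metric_name = metric_name,
         out_dir = config$out_dir),
    class = "ncscreen_run"
  ))
}

#' @export
print.ncscreen_run <- function(x, ...) {
  cat(sprintf("ncscreen pipeline run (%s): %d resamples, K = %d\n",
              x$config$task, length(x$curves), nrow(x$curves[[1L]])))
  print(x$turning_point)
  cat(sprintf("  final model on %d markers: test %s = %.4f\n", x$k_star,
              x$metric_name, x$final_test_metric))
  cat("  artifacts in:", x$out_dir, "\n")
  invisible(x)
}

#' Validate a marker panel on an external cohort
#'
#' Intersects the panel with the features the external cohort actually
#' measures, retrains the binary screening network on the matched markers
#' using the internal training samples, and evaluates AUC on the raw
#' external values - no filtering, outlier removal or normalisation is
#' applied, mirroring the study's stress test of robustness on independent
#' real-world data. A matched panel below 10 markers is flagged as low
#' overlap: small panels were observed to be unstable.
#'
#' @param panel a [marker_panel()] ranked on the internal cohort.
#' @param x internal cohort expression matrix.
#' @param y internal labels aligned to rows.
#' @param split a [split_samples()] result for the internal cohort.
#' @param external_x external cohort expression matrix (raw TPM).
#' @param external_y external labels aligned to its rows.
#' @param config optional [nn_config()] for the retrained model.
#' @param seed integer seed for retraining.
#' @return an object of class `external_validation`: list with
#'   `n_matched`, `missing`, `auc`, `low_overlap` and the retrained
#'   `model`.
#' @export
validate_external <- function(panel, x, y, split, external_x, external_y,
                              config = NULL, seed = 1) {
  stopifnot(inherits(panel, "marker_panel"))
  check_expression_matrix(external_x, "external_x")
  inter <- intersect_markers(external_x, panel)
  feats <- inter$panel$feature_id
  y <- binarize_labels(y)
  ext_y <- binarize_labels(external_y)
  fit <- fit_screen_model("nn", x[split$train, feats, drop = FALSE],
                          y[split$train], config = config,
                          val_x = x[split$val, feats, drop = FALSE],
                          val_y = y[split$val], seed = seed)
  scores <- predict_scores(fit, inter$expression)[, levels(ext_y)[2L]]
  structure(
    list(n_matched = inter$report$n_matched,
         missing = inter$report$missing,
         auc = auc(scores, ext_y),
         low_overlap = inter$report$n_matched < 10L,
         model = fit),
    class = "external_validation"
  )
}

#' @export
print.external_validation <- function(x, ...) {
  cat(sprintf("External validation: %d matched markers (%d missing), AUC = %.4f\n",
              x$n_matched, length(x$missing), x$auc))
  if (x$low_overlap) {
    cat("  WARNING: low marker overlap (< 10); estimates may be unstable\n")
  }
  invisible(x)
}
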