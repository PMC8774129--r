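# Synthetic TPM cohorts with planted informative noncoding-RNA markers.
#
# The generative law is log-normal with multiplicative dropout: TPM is
# non-negative and heavy-tailed, and a fixed fraction of entries is forced to
# zero to emulate unexpressed transcripts. Informative features receive a
# log-scale mean shift in one target cancer class, assigned round-robin so
# every cancer class carries markers once n_informative >= n_classes.

#' Configuration for a synthetic TPM cohort
#'
#' Defines the shape and signal structure of a simulated expression cohort:
#' number of cancer classes (class 0 is always "normal"), per-class sample
#' counts, feature count, how many features are informative, and the
#' log-scale effect size planted in each informative feature's target class.
#'
#' The defaults mirror the structure of a large pan-cancer compendium:
#' 26 cancer types, 632 normal and 8425 tumour samples (about 13:1
#' imbalance). Tests and examples use much smaller configurations.
#'
#' @param n_classes number of cancer classes (excluding normal).
#' @param samples_per_class integer vector of length `n_classes + 1`; the
#'   first entry is the normal-class size.
#' @param n_features number of features (noncoding RNAs).
#' @param n_informative number of planted informative features
#'   (`<= n_features`).
#' @param effect_size non-negative log-scale mean shift applied to an
#'   informative feature in its target class.
#' @param base_log_mean log-scale mean of background expression.
#' @param base_log_sd positive log-scale standard deviation.
#' @param dropout_rate fraction of entries forced to exactly 0 in `[0, 1]`.
#' @param seed integer seed; cohorts are byte-identical for a fixed seed.
#' @return an object of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_classes = 2, samples_per_class = c(50, 50, 50),
#'                         n_features = 200, n_informative = 10,
#'                         effect_size = 3, seed = 7)
synthetic_config <- function(n_classes = 26,
                             samples_per_class = c(632L, rep(324L, 25L), 325L),
                             n_features = 2000,
                             n_informative = 300,
                             effect_size = 1.5,
                             base_log_mean = 1.5,
                             base_log_sd = 1.2,
                             dropout_rate = 0.3,
                             seed = 1) {
  check_scalar(n_classes, "n_classes", integer = TRUE, lower = 1)
  if (!is.numeric(samples_per_class) || any(samples_per_class != round(samples_per_class))) {
    stop("'samples_per_class' must be a vector of integers", call. = FALSE)
  }
  if (length(samples_per_class) != n_classes + 1L) {
    stop("'samples_per_class' must have length n_classes + 1 (normal first)",
         call. = FALSE)
  }
  if (any(samples_per_class < 1)) {
    stop("every class must contain at least one sample", call. = FALSE)
  }
  check_scalar(n_features, "n_features", integer = TRUE, lower = 1)
  check_scalar(n_informative, "n_informative", integer = TRUE, lower = 0)
  if (n_informative > n_features) {
    stop("'n_informative' must not exceed 'n_features'", call. = FALSE)
  }
  check_scalar(effect_size, "effect_size", lower = 0)
  check_scalar(base_log_mean, "base_log_mean")
  check_scalar(base_log_sd, "base_log_sd", lower = 1e-12)
  check_scalar(dropout_rate, "dropout_rate", lower = 0, upper = 1)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(n_classes = as.integer(n_classes),
         samples_per_class = as.integer(samples_per_class),
         n_features = as.integer(n_features),
         n_informative = as.integer(n_informative),
         effect_size = effect_size,
         base_log_mean = base_log_mean,
         base_log_sd = base_log_sd,
         dropout_rate = dropout_rate,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic TPM cohort configuration\n")
  cat(sprintf("  classes: normal + %d cancer types; samples: %d (normal %d)\n",
              x$n_classes, sum(x$samples_per_class), x$samples_per_class[1L]))
  cat(sprintf("  features: %d (%d informative, effect size %.2f on log scale)\n",
              x$n_features, x$n_informative, x$effect_size))
  cat(sprintf("  background: log-normal(%.2f, %.2f), dropout %.2f, seed %d\n",
              x$base_log_mean, x$base_log_sd, x$dropout_rate, x$seed))
  invisible(x)
}

class_names <- function(n_classes) {
  c("normal", sprintf("cancer%02d", seq_len(n_classes)))
}

feature_names <- function(n_features) {
  sprintf("ncRNA_%05d", seq_len(n_features))
}

# core draw shared by the primary and external cohorts
draw_cohort <- function(config, sd_factor = 1, sample_prefix = "S") {
  n_total <- sum(config$samples_per_class)
  classes <- class_names(config$n_classes)
  labels <- rep(classes, times = config$samples_per_class)
  feats <- feature_names(config$n_features)

  # planted markers: round-robin over cancer classes so each type gets some
  truth <- if (config$n_informative > 0L) {
    data.frame(
      feature_id = feats[seq_len(config$n_informative)],
      target_class = classes[-1L][(seq_len(config$n_informative) - 1L) %%
                                    config$n_classes + 1L],
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(feature_id = character(0), target_class = character(0),
               stringsAsFactors = FALSE)
  }

  log_mu <- matrix(config$base_log_mean, nrow = n_total, ncol = config$n_features)
  if (nrow(truth) > 0L && config$effect_size != 0) {
    for (j in seq_len(nrow(truth))) {
      rows <- labels == truth$target_class[j]
      log_mu[rows, j] <- log_mu[rows, j] + config$effect_size
    }
  }
  x <- exp(log_mu + matrix(
    stats::rnorm(n_total * config$n_features, 0, config$base_log_sd * sd_factor),
    nrow = n_total
  ))
  if (config$dropout_rate > 0) {
    x[matrix(stats::runif(length(x)) < config$dropout_rate, nrow = n_total)] <- 0
  }
  rownames(x) <- sprintf("%s%05d", sample_prefix, seq_len(n_total))
  colnames(x) <- feats
  list(expression = x, labels = labels, truth = truth)
}

#' Generate a synthetic TPM cohort
#'
#' Draws a samples-by-features matrix of non-negative TPM-like values from a
#' log-normal background with multiplicative dropout, plants `n_informative`
#' features with a log-scale mean shift in their target cancer classes, and
#' returns the ground truth of the planted markers.
#'
#' @param config a [synthetic_config()].
#' @return a list with components `expression` (numeric matrix, sample
#'   rownames / feature colnames), `labels` (character vector aligned to
#'   rows; `"normal"` or `"cancerNN"`), and `truth` (data.frame with
#'   `feature_id`, `target_class` for the planted markers).
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(
#'   n_classes = 2, samples_per_class = c(20, 20, 20),
#'   n_features = 50, n_informative = 5, effect_size = 2, seed = 1))
#' dim(cohort$expression)
#' table(cohort$labels)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, draw_cohort(config))
}

#' Generate a paired external validation cohort
#'
#' Draws an independent cohort from the same generative law as
#' [generate_cohort()] but exposes only `round(shared_fraction * n_features)`
#' of the original feature identifiers; the remaining features are renamed to
#' non-matching identifiers, emulating an external dataset annotated against
#' a different reference. The log-scale standard deviation is inflated by a
#' fixed factor of 1.5 to emulate the extra variation and outliers typical of
#' independently collected validation data.
#'
#' @param config the [synthetic_config()] used for the primary cohort.
#' @param shared_fraction fraction of feature identifiers kept, in `(0, 1]`.
#' @param id_mangle_seed seed governing which identifiers are kept/renamed.
#' @return a list with `expression` and `labels` as in [generate_cohort()].
#' @export
generate_paired_external_cohort <- function(config, shared_fraction,
                                            id_mangle_seed = config$seed + 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  check_scalar(shared_fraction, "shared_fraction", lower = 1e-12, upper = 1)
  n_shared <- round(shared_fraction * config$n_features)
  if (n_shared < 1L) {
    stop("'shared_fraction' leaves no shared feature identifiers; ",
         "external validation would be impossible", call. = FALSE)
  }
  cohort <- with_seed(derive_seed(config$seed, "external-draw"),
                      draw_cohort(config, sd_factor = 1.5, sample_prefix = "E"))
  feats <- colnames(cohort$expression)
  keep <- with_seed(id_mangle_seed,
                    sort(sample.int(config$n_features, n_shared)))
  renamed <- feats
  drop <- setdiff(seq_len(config$n_features), keep)
  renamed[drop] <- sprintf("ext_%s", feats[drop])
  colnames(cohort$expression) <- renamed
  list(expression = cohort$expression, labels = cohort$labels)
}

#' Write a synthetic cohort to plain-text fixture files
#'
#' Emits `expression.tsv`, `labels.tsv` and, when ground truth is supplied,
#' `truth.tsv` in the formats read back by [read_expression_matrix()],
#' [read_labels()] and [read_marker_truth()]. Values are printed with 17
#' significant digits so a read-back round-trip reproduces them exactly.
#'
#' @param expression samples-by-features numeric matrix.
#' @param labels character vector of class labels aligned to rows.
#' @param truth optional data.frame with `feature_id`, `target_class`.
#' @param directory output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(expression, labels, truth = NULL, directory) {
  if (!is.matrix(expression) || nrow(expression) == 0L) {
    stop("cannot write a fixture with 0 samples", call. = FALSE)
  }
  check_expression_matrix(expression, "expression")
  if (length(labels) != nrow(expression)) {
    stop("'labels' length must equal the number of samples", call. = FALSE)
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  paths <- c(expression = file.path(directory, "expression.tsv"),
             labels = file.path(directory, "labels.tsv"))
  write_expression_matrix(expression, paths[["expression"]])
  write_labels(labels, rownames(expression), paths[["labels"]])
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(directory, "truth.tsv"))
    utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Read planted-marker ground truth
#'
#' @param path path to a `truth.tsv` written by [write_fixture()].
#' @return data.frame with `feature_id` and `target_class`.
#' @export
read_marker_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
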