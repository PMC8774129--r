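# Reading and writing expression matrices, labels and marker panels, the
# 20%/20%/60% sample split, and marker-panel/cohort intersection.
#
# TPM values are read exactly as printed: no normalisation, no filtering and
# no transformation happens on read. An optional log1p transform exists on
# the model side but is off by default.

#' Read a TPM expression matrix from TSV
#'
#' Expects a tab-separated file whose first row is `sample_id` followed by
#' feature identifiers and whose subsequent rows carry a sample identifier
#' then TPM values ('.' decimal separator). Values are returned exactly as
#' printed; row and column order are preserved. Negative values, non-numeric
#' cells and duplicate identifiers are rejected with the offending line and
#' column named.
#'
#' @param path path to the TSV file.
#' @return a numeric matrix with sample rownames and feature colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("expression file needs a sample_id column plus ",
                           "at least one feature column: ", path, call. = FALSE)
  feature_ids <- colnames(raw)[-1L]
  sample_ids <- raw[[1L]]
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature identifier(s) in header: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifier(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  values <- matrix(NA_real_, nrow = nrow(raw), ncol = length(feature_ids),
                   dimnames = list(sample_ids, feature_ids))
  for (j in seq_along(feature_ids)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(col) | !is.finite(col))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value %s at line %d, column '%s' in %s",
                   dQuote(raw[[j + 1L]][bad[1L]]), bad[1L] + 1L,
                   feature_ids[j], path), call. = FALSE)
    }
    neg <- which(col < 0)
    if (length(neg) > 0L) {
      stop(sprintf("negative TPM value %g at line %d, column '%s' in %s",
                   col[neg[1L]], neg[1L] + 1L, feature_ids[j], path),
           call. = FALSE)
    }
    values[, j] <- col
  }
  values
}

#' Write a TPM expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; values are printed with 17
#' significant digits so doubles round-trip exactly.
#'
#' @param x numeric matrix with sample rownames and feature colnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path) {
  check_expression_matrix(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read per-sample class labels
#'
#' @param path TSV with header and two columns, `sample_id` and `label`.
#' @return character vector of labels named by sample identifier.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% colnames(d))) {
    stop("labels file must have columns 'sample_id' and 'label': ", path,
         call. = FALSE)
  }
  stats::setNames(as.character(d$label), d$sample_id)
}

#' Write per-sample class labels
#' @param labels character vector of labels.
#' @param sample_ids sample identifiers aligned to `labels`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_labels <- function(labels, sample_ids, path) {
  stopifnot(length(labels) == length(sample_ids))
  utils::write.table(
    data.frame(sample_id = sample_ids, label = labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Split samples into test, validation and training sets
#'
#' Performs the study's sequential random split: the test set takes
#' `ceiling(test_frac * n)` samples, the validation set
#' `ceiling(val_frac * (n - n_test))` of the remainder, and everything else
#' is training. With `n = 9057` and both fractions 0.2 this yields
#' 1812 / 1449 / 5796. Membership is a uniform random partition,
#' deterministic per seed; no stratification by class unless `labels` is
#' supplied with `stratify = TRUE`.
#'
#' @param n_samples total number of samples (>= 3).
#' @param test_frac fraction held out for the final test set, in (0, 1).
#' @param val_frac fraction of the remainder held out for validation.
#' @param seed integer seed.
#' @param stratify if `TRUE`, allocate each class proportionally (requires
#'   `labels`). Off by default: the study splits sample-wise.
#' @param labels optional class labels of length `n_samples` for
#'   stratification.
#' @return an object of class `data_split` with integer index vectors
#'   `test`, `val`, `train`.
#' @export
#' @examples
#' s <- split_samples(9057, 0.2, 0.2, seed = 1)
#' lengths(s[c("test", "val", "train")])   # 1812 / 1449 / 5796
split_samples <- function(n_samples, test_frac = 0.2, val_frac = 0.2, seed = 1,
                          stratify = FALSE, labels = NULL) {
  check_scalar(n_samples, "n_samples", integer = TRUE, lower = 3)
  check_scalar(test_frac, "test_frac", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar(val_frac, "val_frac", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar(seed, "seed", integer = TRUE)
  n_test <- as.integer(ceiling(test_frac * n_samples))
  n_val <- as.integer(ceiling(val_frac * (n_samples - n_test)))
  n_train <- n_samples - n_test - n_val
  if (n_test < 1L || n_val < 1L || n_train < 1L) {
    stop("split fractions leave an empty set (test ", n_test, ", val ", n_val,
         ", train ", n_train, ")", call. = FALSE)
  }
  idx <- if (stratify) {
    if (is.null(labels) || length(labels) != n_samples) {
      stop("'stratify = TRUE' requires 'labels' of length n_samples",
           call. = FALSE)
    }
    # proportional allocation within class, then pool and re-shuffle order
    with_seed(seed, {
      perm <- unlist(lapply(split(seq_len(n_samples), labels), sample),
                     use.names = FALSE)
      perm[order(stats::runif(n_samples))]
    })
  } else {
    with_seed(seed, sample.int(n_samples))
  }
  structure(
    list(test = sort(idx[seq_len(n_test)]),
         val = sort(idx[n_test + seq_len(n_val)]),
         train = sort(idx[(n_test + n_val) + seq_len(n_train)]),
         seed = as.integer(seed),
         fractions = c(test = test_frac, val = val_frac)),
    class = "data_split"
  )
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("Sample split (seed %d): test %d / val %d / train %d\n",
              x$seed, length(x$test), length(x$val), length(x$train)))
  invisible(x)
}

#' Construct a ranked marker panel
#'
#' A marker panel is an ordered table of feature identifiers with frequency
#' scores (selection rates over resampling runs), sorted by non-increasing
#' score with ties broken by ascending feature identifier.
#'
#' @param feature_id character vector of unique feature identifiers.
#' @param frequency_score numeric scores in `[0, 1]` aligned to
#'   `feature_id`.
#' @param selected optional logical flag marking the final biomarker set.
#' @param provenance free-text description of the selection parameters.
#' @return a data.frame of class `marker_panel` with columns `feature_id`,
#'   `frequency_score`, `rank` (and `selected` when given).
#' @export
marker_panel <- function(feature_id, frequency_score,
                         selected = NULL, provenance = "") {
  stopifnot(length(feature_id) == length(frequency_score))
  if (anyDuplicated(feature_id)) {
    stop("duplicate feature_id in marker panel", call. = FALSE)
  }
  if (length(frequency_score) && (any(frequency_score < 0) || any(frequency_score > 1))) {
    stop("frequency scores must lie in [0, 1]", call. = FALSE)
  }
  ord <- order(-frequency_score, feature_id)
  panel <- data.frame(feature_id = as.character(feature_id)[ord],
                      frequency_score = as.numeric(frequency_score)[ord],
                      rank = seq_along(ord),
                      stringsAsFactors = FALSE)
  if (!is.null(selected)) panel$selected <- as.logical(selected)[ord]
  attr(panel, "provenance") <- provenance
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' @export
print.marker_panel <- function(x, n = 10L, ...) {
  cat(sprintf("Marker panel: %d features", nrow(x)))
  if ("selected" %in% colnames(x)) {
    cat(sprintf(" (%d in final set)", sum(x$selected)))
  }
  cat("\n")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("... and %d more\n", nrow(x) - n))
  invisible(x)
}

#' Read / write a marker panel TSV
#'
#' The on-disk format is a TSV with header `feature_id`, `frequency_score`,
#' `rank`. Reading re-validates the ordering invariant (non-increasing
#' score, ties by ascending identifier, no duplicates) and fails on files
#' that violate it.
#'
#' @param path file path.
#' @return `read_marker_panel` returns a [marker_panel()];
#'   `write_marker_panel` invisibly returns `path`.
#' @export
read_marker_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "frequency_score", "rank")
  if (!all(need %in% colnames(d))) {
    stop("marker panel file must have columns ", paste(need, collapse = ", "),
         ": ", path, call. = FALSE)
  }
  if (anyDuplicated(d$feature_id)) {
    stop("duplicate feature_id entries in marker panel file: ", path,
         call. = FALSE)
  }
  if (is.unsorted(rev(d$frequency_score))) {
    stop("marker panel file is not sorted by non-increasing frequency_score: ",
         path, call. = FALSE)
  }
  sel <- if ("selected" %in% colnames(d)) as.logical(d$selected) else NULL
  panel <- marker_panel(d$feature_id, d$frequency_score, selected = sel)
  if (!identical(panel$feature_id, d$feature_id)) {
    stop("marker panel file violates the tie-break order ",
         "(ascending feature_id within equal scores): ", path, call. = FALSE)
  }
  panel
}

#' @rdname read_marker_panel
#' @param panel a [marker_panel()].
#' @export
write_marker_panel <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Intersect a marker panel with a cohort's features
#'
#' Restricts an expression matrix to the panel features it actually
#' measures, in panel order, preserving the original frequency scores.
#' Mirrors external validation against cohorts annotated on a different
#' reference, where only a subset of panel markers is compatible. Features
#' missing from the cohort are dropped, not zero-imputed.
#'
#' @param x samples-by-features expression matrix.
#' @param panel a [marker_panel()].
#' @return a list with `expression` (restricted matrix, columns in panel
#'   order), `panel` (matched sub-panel), and `report` (list with
#'   `n_matched`, `n_missing`, `missing` identifiers).
#' @export
intersect_markers <- function(x, panel) {
  check_expression_matrix(x)
  stopifnot(inherits(panel, "marker_panel"))
  present <- panel$feature_id %in% colnames(x)
  if (!any(present)) {
    stop("no panel marker is measured in this cohort; ",
         "external validation is impossible without at least one shared ",
         "feature identifier", call. = FALSE)
  }
  matched <- marker_panel(panel$feature_id[present],
                          panel$frequency_score[present],
                          selected = if ("selected" %in% colnames(panel))
                            panel$selected[present] else NULL,
                          provenance = attr(panel, "provenance"))
  list(
    expression = x[, panel$feature_id[present], drop = FALSE],
    panel = matched,
    report = list(n_matched = sum(present),
                  n_missing = sum(!present),
                  missing = panel$feature_id[!present])
  )
}
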