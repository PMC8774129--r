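# Conventional machine-learning baselines used for model comparison.
# Random forest and a single decision tree are fitted with standard library
# implementations at default hyperparameters, seeded, and wrapped so that
# evaluation code can score any model kind through the same contract.

#' Fit a baseline classifier
#'
#' @param kind `"random_forest"` (randomForest at defaults) or
#'   `"decision_tree"` (rpart classification tree at defaults, no
#'   cross-validation pruning so fits are deterministic).
#' @param x training matrix (samples x features, feature colnames).
#' @param y class labels aligned to rows (coerced to factor).
#' @param seed integer seed.
#' @param ... passed to the underlying fitter: [randomForest::randomForest()]
#'   arguments, or [rpart::rpart.control()] options such as `maxdepth`.
#' @return an object of class `screen_baseline` exposing the same
#'   [predict_scores()] contract as the neural network.
#' @export
fit_baseline <- function(kind = c("random_forest", "decision_tree"),
                         x, y, seed = 1, ...) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  check_scalar(seed, "seed", integer = TRUE)
  # rpart needs syntactic variable names; keep a stable mapping
  safe <- sprintf("V%d", seq_len(ncol(x)))
  fit <- if (kind == "random_forest") {
    with_seed(seed, randomForest::randomForest(x = x, y = y, ...))
  } else {
    d <- data.frame(.class = y, x, check.names = FALSE)
    colnames(d) <- c(".class", safe)
    with_seed(seed, rpart::rpart(.class ~ ., data = d, method = "class",
                                 control = rpart::rpart.control(xval = 0, ...)))
  }
  structure(
    list(fit = fit, kind = kind, feature_ids = colnames(x),
         safe_names = safe, classes = levels(y), seed = as.integer(seed)),
    class = "screen_baseline"
  )
}

#' @export
print.screen_baseline <- function(x, ...) {
  cat(sprintf("Baseline %s: %d features, classes: %s\n", x$kind,
              length(x$feature_ids), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Class-probability scores from any screening model
#'
#' Model-agnostic scoring used by the evaluation layer: every model kind
#' returns a samples-by-classes probability matrix (binary models included,
#' so the positive-class column can be read off uniformly). Columns of
#' `newdata` are realigned by feature identifier.
#'
#' @param model a fitted `cancer_nn` or `screen_baseline`.
#' @param newdata samples-by-features matrix.
#' @return numeric matrix of class probabilities, columns named by class.
#' @export
predict_scores <- function(model, newdata) UseMethod("predict_scores")

#' @export
predict_scores.cancer_nn <- function(model, newdata) {
  if (model$config$task == "binary") {
    p <- predict(model, newdata, type = "prob")
    out <- cbind(1 - p, p)
    colnames(out) <- model$classes
    out
  } else {
    predict(model, newdata, type = "prob")
  }
}

#' @export
predict_scores.screen_baseline <- function(model, newdata) {
  x <- align_features(newdata, model$feature_ids)
  p <- if (model$kind == "random_forest") {
    stats::predict(model$fit, x, type = "prob")
  } else {
    nd <- as.data.frame(x)
    colnames(nd) <- model$safe_names
    stats::predict(model$fit, nd, type = "prob")
  }
  p[, model$classes, drop = FALSE]
}

# fit any supported model kind through one entry point (evaluation layer)
fit_screen_model <- function(kind, x, y, config = NULL, val_x = NULL,
                             val_y = NULL, seed = 1) {
  if (kind == "nn") {
    if (is.null(config)) {
      task <- if (nlevels(as.factor(y)) == 2L) "binary" else "multiclass"
      config <- nn_config(task, seed = seed)
    } else {
      config$seed <- as.integer(seed)
    }
    fit_nn(x, y, config, val_x = val_x, val_y = val_y)
  } else {
    fit_baseline(kind, x, y, seed = seed)
  }
}
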