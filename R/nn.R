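# Fixed-architecture feed-forward neural networks for cancer screening.
#
# Two architectures are used throughout: a binary cancer-vs-normal net with
# dense layers of 30 and 60 units and a single sigmoid output, and a 26-way
# net with six hidden layers of 240 units and a softmax head. Every dense
# layer except the output is followed by relu and dropout (rate 0.1).
# Training is plain mini-batch Adam on cross-entropy for a fixed number of
# epochs (30) with batch size 20 and no early stopping. The trainer is
# implemented here in base R matrix arithmetic; it is deliberately small and
# fully deterministic per seed (weight initialisation, epoch shuffling and
# dropout masks all come from the model's own seeded stream).

#' Neural-network configuration
#'
#' @param task `"binary"` (cancer vs normal; sigmoid output) or
#'   `"multiclass"` (one softmax unit per cancer type).
#' @param layer_widths dense-layer widths before the output head. Defaults:
#'   `c(30, 60)` for binary, `rep(240, 6)` for multiclass.
#' @param dropout_rate dropout applied after every dense layer except the
#'   output, in `[0, 1)`. Default 0.1.
#' @param activation hidden activation; only `"relu"` is supported.
#' @param optimizer only `"adam"` is supported (learning rate 0.001,
#'   beta1 0.9, beta2 0.999).
#' @param learning_rate Adam step size.
#' @param epochs fixed number of training epochs (default 30).
#' @param batch_size mini-batch size (default 20).
#' @param transform `"none"` (raw TPM in, as the study feeds its models) or
#'   `"log1p"` for experimentation with compressed inputs.
#' @param class_weight if `TRUE`, weight the loss inversely to class
#'   frequency. Off by default: the study uses none despite the ~13:1
#'   imbalance.
#' @param seed integer seed for initialisation, shuffling and dropout.
#' @return an object of class `nn_config`.
#' @export
nn_config <- function(task = c("binary", "multiclass"),
                      layer_widths = NULL,
                      dropout_rate = 0.1,
                      activation = "relu",
                      optimizer = "adam",
                      learning_rate = 0.001,
                      epochs = 30L,
                      batch_size = 20L,
                      transform = c("none", "log1p"),
                      class_weight = FALSE,
                      seed = 1) {
  task <- match.arg(task)
  if (is.null(layer_widths)) {
    layer_widths <- if (task == "binary") c(30L, 60L) else rep(240L, 6L)
  }
  if (any(layer_widths < 1) || any(layer_widths != round(layer_widths))) {
    stop("'layer_widths' must be positive integers", call. = FALSE)
  }
  check_scalar(dropout_rate, "dropout_rate", lower = 0, upper = 1 - 1e-12)
  activation <- match.arg(activation, "relu")
  optimizer <- match.arg(optimizer, "adam")
  check_scalar(learning_rate, "learning_rate", lower = 1e-12)
  check_scalar(epochs, "epochs", integer = TRUE, lower = 1)
  check_scalar(batch_size, "batch_size", integer = TRUE, lower = 1)
  transform <- match.arg(transform)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(task = task, layer_widths = as.integer(layer_widths),
         dropout_rate = dropout_rate, activation = activation,
         optimizer = optimizer, learning_rate = learning_rate,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         transform = transform, class_weight = isTRUE(class_weight),
         seed = as.integer(seed)),
    class = "nn_config"
  )
}

#' @export
print.nn_config <- function(x, ...) {
  cat(sprintf(
    "NN config (%s): layers [%s] + %s head, dropout %.2f, %s/%s lr %.4g,\n  epochs %d, batch %d, transform %s, seed %d\n",
    x$task, paste(x$layer_widths, collapse = ", "),
    if (x$task == "binary") "sigmoid" else "softmax",
    x$dropout_rate, x$activation, x$optimizer, x$learning_rate,
    x$epochs, x$batch_size, x$transform, x$seed))
  invisible(x)
}

# Glorot-uniform initialised weights for the dense stack
init_weights <- function(n_features, n_out, widths) {
  dims <- c(n_features, widths, n_out)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    fan_in <- dims[l]
    fan_out <- dims[l + 1L]
    limit <- sqrt(6 / (fan_in + fan_out))
    W[[l]] <- matrix(stats::runif(fan_in * fan_out, -limit, limit),
                     nrow = fan_in, ncol = fan_out)
    b[[l]] <- numeric(fan_out)
  }
  list(W = W, b = b)
}

#' Build an untrained neural network
#'
#' Instantiates the dense stack with seeded Glorot-uniform weights. The
#' output head is a single sigmoid unit for binary classification or an
#' `n_classes`-way softmax for the multi-cancer classifier.
#'
#' @param n_features number of input features.
#' @param n_classes number of classes (2 for binary).
#' @param config an [nn_config()].
#' @return an object of class `nn_model` (untrained) with weight matrices
#'   `W`, biases `b`, and the configuration.
#' @export
build_nn <- function(n_features, n_classes, config = nn_config()) {
  stopifnot(inherits(config, "nn_config"))
  check_scalar(n_features, "n_features", integer = TRUE, lower = 1)
  check_scalar(n_classes, "n_classes", integer = TRUE, lower = 2)
  if (config$task == "binary" && n_classes != 2L) {
    stop("binary task requires n_classes = 2", call. = FALSE)
  }
  n_out <- if (config$task == "binary") 1L else as.integer(n_classes)
  pars <- with_seed(config$seed,
                    init_weights(n_features, n_out, config$layer_widths))
  structure(
    list(W = pars$W, b = pars$b, n_features = as.integer(n_features),
         n_classes = as.integer(n_classes), config = config),
    class = "nn_model"
  )
}

#' Number of trainable parameters in a network
#' @param model an `nn_model` or fitted `cancer_nn`.
#' @return integer count of weights plus biases.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$W, length, 0L)) + sum(vapply(model$b, length, 0L))
}

relu <- function(z) z * (z > 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; when train = TRUE applies inverted dropout with the masks
# drawn from the current RNG stream and returns the caches needed by
# backprop
nn_forward <- function(W, b, x, config, train = FALSE) {
  L <- length(W)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  M <- vector("list", L)
  A[[1L]] <- x
  keep <- 1 - config$dropout_rate
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% W[[l]], 2L, b[[l]], "+")
    if (l < L) {
      a <- relu(Z[[l]])
      if (train && config$dropout_rate > 0) {
        M[[l]] <- matrix(stats::runif(length(a)) < keep, nrow = nrow(a)) / keep
        a <- a * M[[l]]
      }
      A[[l + 1L]] <- a
    } else {
      A[[l + 1L]] <- if (config$task == "binary") {
        stats::plogis(Z[[l]])
      } else {
        softmax_rows(Z[[l]])
      }
    }
  }
  list(A = A, Z = Z, M = M, out = A[[L + 1L]])
}

# cross-entropy loss and accuracy; Y is a 0/1 vector (binary) or a one-hot
# matrix (multiclass); w optional per-sample weights summing to n
nn_loss_acc <- function(out, Y, task, w = NULL) {
  eps <- 1e-12
  if (task == "binary") {
    p <- pmin(pmax(out[, 1L], eps), 1 - eps)
    ll <- -(Y * log(p) + (1 - Y) * log(1 - p))
    acc <- mean((p > 0.5) == (Y == 1))
  } else {
    p <- pmin(pmax(rowSums(out * Y), eps), 1)
    ll <- -log(p)
    acc <- mean(max.col(out) == max.col(Y))
  }
  loss <- if (is.null(w)) mean(ll) else sum(w * ll) / length(ll)
  c(loss = loss, acc = acc)
}

adam_init <- function(W, b) {
  list(mW = lapply(W, function(w) w * 0), vW = lapply(W, function(w) w * 0),
       mb = lapply(b, function(x) x * 0), vb = lapply(b, function(x) x * 0),
       t = 0L)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(par$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grad$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grad$dW[[l]]^2
    par$W[[l]] <- par$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grad$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grad$db[[l]]^2
    par$b[[l]] <- par$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(par = par, state = state)
}

# backprop for one mini-batch; Y as in nn_loss_acc, w optional sample weights
nn_backward <- function(W, fwd, Y, task, w = NULL) {
  L <- length(W)
  n <- nrow(fwd$A[[1L]])
  dZ <- if (task == "binary") {
    matrix((fwd$out[, 1L] - Y) / n, ncol = 1L)
  } else {
    (fwd$out - Y) / n
  }
  if (!is.null(w)) dZ <- dZ * w
  dW <- vector("list", L)
  db <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fwd$A[[l]], dZ)
    db[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- dZ %*% t(W[[l]])
      if (!is.null(fwd$M[[l - 1L]])) dA <- dA * fwd$M[[l - 1L]]
      dZ <- dA * (fwd$Z[[l - 1L]] > 0)
    }
  }
  list(dW = dW, db = db)
}

encode_labels <- function(y, classes, task) {
  y <- as.character(y)
  bad <- setdiff(unique(y), classes)
  if (length(bad) > 0L) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (task == "binary") {
    as.numeric(y == classes[2L])
  } else {
    Y <- matrix(0, nrow = length(y), ncol = length(classes),
                dimnames = list(NULL, classes))
    Y[cbind(seq_along(y), match(y, classes))] <- 1
    Y
  }
}

#' Fit a cancer-screening neural network
#'
#' Trains the fixed-architecture feed-forward network on a
#' samples-by-features TPM matrix for exactly `config$epochs` epochs of
#' mini-batch Adam on cross-entropy, with per-epoch shuffling and no early
#' stopping, and records the full training history. Inputs are fed raw
#' (no normalisation) unless `config$transform = "log1p"`.
#'
#' @param x numeric training matrix (samples x features, feature colnames).
#' @param y class labels aligned to rows. For the binary task supply a
#'   factor with two levels (second level = positive class, typically
#'   "cancer"); see [binarize_labels()].
#' @param config an [nn_config()].
#' @param val_x,val_y optional validation set monitored each epoch.
#' @return an object of class `cancer_nn` with the trained weights, the
#'   feature/class order, the configuration and a `history` data.frame
#'   (`epoch`, `loss`, `acc`, `val_loss`, `val_acc`).
#' @seealso [predict.cancer_nn()], [plot.cancer_nn()]
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rexp(200), 100, 2, dimnames = list(NULL, c("f1", "f2")))
#' y <- factor(ifelse(x[, 1] > 1, "cancer", "normal"),
#'             levels = c("normal", "cancer"))
#' fit <- fit_nn(x, y, nn_config("binary", epochs = 5, seed = 1))
#' fit$history$acc
fit_nn <- function(x, y, config = nn_config(), val_x = NULL, val_y = NULL) {
  stopifnot(inherits(config, "nn_config"))
  if (!is.matrix(x) || is.null(colnames(x))) {
    stop("'x' must be a matrix with feature colnames", call. = FALSE)
  }
  y <- as.factor(y)
  classes <- levels(y)
  if (config$task == "binary" && length(classes) != 2L) {
    stop("binary task requires exactly 2 label levels", call. = FALSE)
  }
  if (config$task == "multiclass" && length(classes) < 2L) {
    stop("multiclass task requires at least 2 label levels", call. = FALSE)
  }
  model <- build_nn(ncol(x), length(classes), config)
  xt <- if (config$transform == "log1p") log1p(x) else x
  Y <- encode_labels(y, classes, config$task)
  have_val <- !is.null(val_x) && !is.null(val_y)
  if (have_val) {
    val_x <- align_features(val_x, colnames(x))
    val_xt <- if (config$transform == "log1p") log1p(val_x) else val_x
    val_Y <- encode_labels(as.character(val_y), classes, config$task)
  }
  w <- NULL
  if (config$class_weight) {
    tab <- table(y)
    wc <- as.numeric(sum(tab) / (length(tab) * tab))
    w <- wc[as.integer(y)]
  }

  W <- model$W
  b <- model$b
  state <- adam_init(W, b)
  n <- nrow(xt)
  hist <- matrix(NA_real_, nrow = config$epochs, ncol = 4L,
                 dimnames = list(NULL, c("loss", "acc", "val_loss", "val_acc")))
  with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        rows <- perm[s:min(s + config$batch_size - 1L, n)]
        xb <- xt[rows, , drop = FALSE]
        Yb <- if (config$task == "binary") Y[rows] else Y[rows, , drop = FALSE]
        wb <- if (is.null(w)) NULL else w[rows]
        fwd <- nn_forward(W, b, xb, config, train = TRUE)
        grad <- nn_backward(W, fwd, Yb, config$task, wb)
        upd <- adam_step(list(W = W, b = b), grad, state,
                         lr = config$learning_rate)
        W <- upd$par$W
        b <- upd$par$b
        state <- upd$state
      }
      tr <- nn_loss_acc(nn_forward(W, b, xt, config)$out, Y, config$task, w)
      hist[epoch, 1:2] <- tr
      if (!is.finite(tr[["loss"]])) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; raw TPM scales vary widely - consider nn_config(transform =",
             " \"log1p\") or a smaller learning rate", call. = FALSE)
      }
      if (have_val) {
        hist[epoch, 3:4] <-
          nn_loss_acc(nn_forward(W, b, val_xt, config)$out, val_Y, config$task)
      }
    }
  })
  structure(
    list(W = W, b = b, feature_ids = colnames(x), classes = classes,
         n_features = ncol(x), n_classes = length(classes), config = config,
         history = data.frame(epoch = seq_len(config$epochs), hist)),
    class = "cancer_nn"
  )
}

# reorder newdata columns to the training feature order, failing on any
# missing feature
align_features <- function(x, feature_ids) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(colnames(x))) {
    if (ncol(x) != length(feature_ids)) {
      stop("newdata has ", ncol(x), " columns but the model expects ",
           length(feature_ids), call. = FALSE)
    }
    colnames(x) <- feature_ids
    return(x)
  }
  missing <- setdiff(feature_ids, colnames(x))
  if (length(missing) > 0L) {
    stop("newdata is missing feature column(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L),
         call. = FALSE)
  }
  x[, feature_ids, drop = FALSE]
}

#' Predict from a fitted cancer-screening network
#'
#' Columns of `newdata` are realigned to the training feature order by
#' identifier; a missing feature is an error naming it. Dropout is never
#' applied at prediction time.
#'
#' @param object a fitted `cancer_nn`.
#' @param newdata samples-by-features matrix.
#' @param type `"prob"` for probabilities (binary: the positive-class
#'   probability per sample; multiclass: a samples-by-classes matrix whose
#'   rows sum to 1), or `"class"` for hard labels.
#' @param ... unused.
#' @return numeric vector, matrix or character vector per `type`.
#' @export
predict.cancer_nn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- align_features(newdata, object$feature_ids)
  if (object$config$transform == "log1p") x <- log1p(x)
  out <- nn_forward(object$W, object$b, x, object$config)$out
  if (object$config$task == "binary") {
    p <- stats::setNames(out[, 1L], rownames(newdata))
    if (type == "prob") p else
      object$classes[as.integer(p > 0.5) + 1L]
  } else {
    colnames(out) <- object$classes
    rownames(out) <- rownames(newdata)
    if (type == "prob") out else object$classes[max.col(out)]
  }
}

#' @export
print.cancer_nn <- function(x, ...) {
  cat(sprintf("Cancer-screening NN (%s): %d features -> [%s] -> %s, %d parameters\n",
              x$config$task, x$n_features,
              paste(x$config$layer_widths, collapse = ", "),
              if (x$config$task == "binary") "sigmoid" else
                sprintf("softmax(%d)", x$n_classes),
              n_parameters(x)))
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  final epoch %d: loss %.4f, accuracy %.4f", h$epoch, h$loss, h$acc))
  if (!is.na(h$val_loss)) {
    cat(sprintf(" (validation loss %.4f, accuracy %.4f)", h$val_loss, h$val_acc))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.cancer_nn <- function(object, ...) {
  print(object)
  cat("Classes:", paste(object$classes, collapse = ", "), "\n")
  cat("Training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5L), row.names = FALSE)
  invisible(object)
}

#' Plot training history
#'
#' Loss and accuracy per epoch for training and, when monitored,
#' validation.
#'
#' @param x a fitted `cancer_nn`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cancer_nn <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$loss, h$val_loss), type = "l", lty = 1,
                    col = c("black", "firebrick"), xlab = "epoch",
                    ylab = "cross-entropy loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$acc, h$val_acc), type = "l", lty = 1,
                    col = c("black", "firebrick"), xlab = "epoch",
                    ylab = "accuracy", ...)
  invisible(x)
}

#' Collapse multi-cancer labels to a binary screening factor
#'
#' @param labels character labels where `"normal"` marks controls.
#' @param positive_label name for the pooled cancer class.
#' @return factor with levels `c("normal", positive_label)`.
#' @export
binarize_labels <- function(labels, positive_label = "cancer") {
  factor(ifelse(as.character(labels) == "normal", "normal", positive_label),
         levels = c("normal", positive_label))
}
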