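# Internal helpers shared across modules.

#' Evaluate code under a local RNG seed
#'
#' Saves and restores the global random seed so seeded package functions do
#' not disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps (master seed, stage label) to an integer in
#' `[1, 2^31 - 2]` so each pipeline stage and resample gets an independent,
#' reproducible stream.
#'
#' @param seed master integer seed.
#' @param stage character label of the stage (e.g. `"resample3"`).
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(42, "split")
#' derive_seed(42, "resample1")
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # 64-bit-safe congruential mix kept inside 2^31 - 1 (R integers are 32-bit)
  m <- 2147483647
  x <- (as.numeric(seed) %% m) * 48271 %% m
  x <- (x + h * 69621) %% m
  x <- (x * 16807 + 1) %% m
  as.integer(x %% (m - 2)) + 1L
}

# single-value numeric checks used by constructors
check_scalar <- function(x, name, integer = FALSE, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s]", name, lower, upper), call. = FALSE)
  }
  invisible(x)
}

# validate an expression matrix: numeric, finite, non-negative, unique ids
check_expression_matrix <- function(x, name = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix (samples x features)", name),
         call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("'%s' must carry sample rownames and feature colnames", name),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop(sprintf("duplicate sample identifiers in '%s'", name), call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop(sprintf("duplicate feature identifiers in '%s'", name), call. = FALSE)
  }
  if (any(!is.finite(x))) stop(sprintf("non-finite values in '%s'", name), call. = FALSE)
  if (any(x < 0)) stop(sprintf("negative TPM values in '%s'", name), call. = FALSE)
  invisible(x)
}
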