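# Internal helpers shared across modules.

#' Evaluate an expression under a fixed, restorable RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that (a) a given seed yields identical results regardless of
#' the caller's RNG state and (b) the caller's RNG state is untouched.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", sample.kind = "Rejection")
  expr
}

#' Derive child seeds from a master seed, each below 2^31
#' @noRd
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max, n))
}

stop_value <- function(...) stop(..., call. = FALSE)

#' Check that a matrix is numeric and fully finite
#' @noRd
assert_finite_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_value(what, " must be a numeric matrix")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop_value(what, " contains non-finite values")
  }
  invisible(x)
}

#' Row-wise Euclidean norms
#' @noRd
row_norms <- function(x) sqrt(rowSums(x * x))

#' Normalize matrix rows to unit length; zero rows stay zero
#' @noRd
normalize_rows <- function(x) {
  nrm <- row_norms(x)
  nz <- nrm > 0
  x[nz, ] <- x[nz, , drop = FALSE] / nrm[nz]
  x
}
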