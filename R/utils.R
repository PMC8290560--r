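# internal helpers shared across modules

`%||%` <- rlang::`%||%`

#' Bend a symmetric matrix to positive definiteness
#'
#' Covariance matrices read from rounded published tables, or estimated on
#' small samples, can carry small negative eigenvalues. Bending floors the
#' eigenvalues at a small positive fraction of the largest one and
#' reconstructs the matrix, the standard remedy for indefinite genetic
#' (co)variance estimates.
#'
#' @param x symmetric numeric matrix.
#' @param floor_frac eigenvalue floor as a fraction of the largest eigenvalue.
#' @return A positive-definite matrix of the same dimension. If `x` is already
#'   positive definite it is returned unchanged.
#' @export
bend_matrix <- function(x, floor_frac = 1e-3) {
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  x <- (x + t(x)) / 2
  e <- eigen(x, symmetric = TRUE)
  lo <- floor_frac * max(e$values)
  if (min(e$values) >= lo) {
    return(x)
  }
  v <- pmax(e$values, lo)
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

is_pd <- function(x, tol = 1e-10) {
  e <- eigen((x + t(x)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(e) > tol * max(abs(e))
}

assert_pd <- function(x, label) {
  if (!is_pd(x)) {
    e <- eigen((x + t(x)) / 2, symmetric = TRUE, only.values = TRUE)$values
    abort(sprintf(
      "%s must be positive definite; eigenvalues: %s",
      label, paste(signif(e, 4), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

# deterministic 32-bit sub-seed derived from a master seed and a stream label
derive_seed <- function(seed, stream) {
  h <- digest::digest(list(as.integer(seed), as.character(stream)), algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), 16L))
}

chol_solve <- function(R, b) backsolve(R, backsolve(R, b, transpose = TRUE))
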