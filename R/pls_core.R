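#' Soft-thresholding operator
#'
#' Elementwise shrink-toward-zero operator
#' \eqn{S_\lambda(x) = \mathrm{sign}(x)\,(|x| - \lambda)_+}, used to zero weak
#' entries of the cross-covariance matrices before their SVD.
#'
#' @param x numeric scalar, vector or matrix.
#' @param lambda non-negative threshold.
#' @return object of the same shape as `x`.
#' @examples
#' soft_threshold(c(-0.8, 0.2, 0.5), 0.3)  # -0.5, 0, 0.2
#' @export
soft_threshold <- function(x, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) || lambda < 0)
    stop_parameter("'lambda' must be a single non-negative number")
  sign(x) * pmax(abs(x) - lambda, 0)
}

#' Cross-covariance between response and each block
#'
#' For standardized data the entries of
#' \eqn{Y^\top X_t / (n-1)} are Pearson correlations in \eqn{[-1, 1]}.
#'
#' @param data a standardized [block_dataset()] (see [standardize()]).
#' @return object of class `cross_covariance`: list with `blocks` (named list
#'   of `q x p_t` matrices) and `col_max` (named list of per-column maximum
#'   absolute entries).
#' @export
cross_covariance <- function(data) {
  stopifnot(inherits(data, "block_dataset"))
  n <- nrow(data$response)
  if (n < 2) stop_degenerate("need n >= 2 for a cross-covariance")
  blocks <- lapply(data$blocks, function(b) crossprod(data$response, b) / (n - 1))
  structure(
    list(blocks = blocks,
         col_max = lapply(blocks, function(m) apply(abs(m), 2, max))),
    class = "cross_covariance"
  )
}

#' Data-driven threshold for a covariate budget
#'
#' Finds the smallest \eqn{\lambda \ge 0} such that the cumulative number of
#' non-null columns of \eqn{S_\lambda(Y^\top X_t/(n-1))} across blocks is at
#' most `L0`, enumerating candidate values over the distinct per-column
#' maximum absolute entries. A column is non-null iff its maximum absolute
#' entry strictly exceeds \eqn{\lambda} (at equality \eqn{(|x|-\lambda)_+ = 0}).
#' When a count of exactly `L0` is attainable it is attained; under ties in
#' column maxima the largest attainable count \eqn{\le} `L0` results.
#'
#' @param cc a [cross_covariance()].
#' @param L0 positive integer covariate budget.
#' @return list with `lambda`, `n_selected` (surviving column count) and
#'   `selected` (named list, per block, of surviving column indices).
#' @export
select_lambda <- function(cc, L0) {
  stopifnot(inherits(cc, "cross_covariance"))
  if (!is.numeric(L0) || length(L0) != 1 || L0 < 1 || L0 != round(L0))
    stop_parameter("'L0' must be a positive integer")
  col_max <- unlist(cc$col_max, use.names = FALSE)
  if (all(col_max == 0))
    stop_no_signal("all cross-covariance entries are zero; nothing to select")
  candidates <- sort(unique(c(0, col_max)))
  counts <- vapply(candidates, function(l) sum(col_max > l), integer(1))
  lambda <- candidates[which(counts <= L0)[1]]  # counts are non-increasing
  list(
    lambda = lambda,
    n_selected = sum(col_max > lambda),
    selected = lapply(cc$col_max, function(cm) which(cm > lambda))
  )
}

# Internal: sign convention for singular-vector columns -- the
# largest-magnitude entry of each non-zero column is made positive, so weights
# and reported coefficient signs are reproducible across platforms.
.fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    if (any(v != 0)) {
      i <- which.max(abs(v))
      if (v[i] < 0) V[, j] <- -v
    }
  }
  V
}

#' Per-block weights from the thresholded cross-covariance
#'
#' Columns of `Ut` are the top-`R` right singular vectors of the block's
#' soft-thresholded cross-covariance matrix; columns beyond the matrix rank
#' are zero (no more components than the rank, itself bounded by `q`). Rows
#' belonging to columns zeroed by the threshold are exactly zero.
#'
#' @param cc_thresholded `q x p_t` thresholded cross-covariance of one block.
#' @param R positive integer component count, `R <= q`.
#' @return `p_t x R` weight matrix with orthonormal non-zero columns.
#' @export
block_weights <- function(cc_thresholded, R) {
  m <- as.matrix(cc_thresholded)
  if (R < 1 || R != round(R)) stop_parameter("'R' must be a positive integer")
  if (R > nrow(m))
    stop_parameter(sprintf("R = %d exceeds the response dimension q = %d", R, nrow(m)))
  U <- matrix(0, ncol(m), R)
  rownames(U) <- colnames(m)
  if (any(m != 0)) {
    s <- svd(m, nu = 0, nv = min(R, nrow(m), ncol(m)))
    rank <- sum(s$d > 1e-12 * s$d[1])
    k <- min(R, rank)
    if (k > 0) U[, seq_len(k)] <- s$v[, seq_len(k), drop = FALSE]
    dead <- apply(m, 2, function(col) all(col == 0))
    U[dead, ] <- 0  # enforce exact zeros for thresholded-out covariates
  }
  .fix_signs(U)
}

#' Super-weights aggregating block scores
#'
#' Second-level, unthresholded application of the same construction one level
#' up: the top-`R` right singular vectors of
#' \eqn{Y^\top Z / (n-1)}, where `Z` is the `n x (T R)` concatenation of the
#' block scores \eqn{X_t U_t}, partitioned into `T` consecutive `R x R`
#' slices \eqn{\beta_t}. The super-components are `Z` times the stacked
#' super-weights, an `n x R` matrix shared by all blocks.
#'
#' @param block_scores `n x (T R)` matrix of concatenated block scores.
#' @param Y_std `n x q` standardized response.
#' @param R component count.
#' @return list with `stacked` (`(T R) x R` matrix) and `beta` (list of `T`
#'   `R x R` slices).
#' @export
super_weights <- function(block_scores, Y_std, R) {
  Z <- as.matrix(block_scores); Y <- as.matrix(Y_std)
  if (nrow(Z) != nrow(Y)) stop_schema("block scores and response row counts differ")
  if (ncol(Z) %% R != 0) stop_schema("score column count is not a multiple of R")
  T_blocks <- ncol(Z) %/% R
  n <- nrow(Z)
  omega <- crossprod(Y, Z) / (n - 1)  # q x (T R)
  W <- matrix(0, ncol(Z), R)
  if (any(omega != 0)) {
    s <- svd(omega, nu = 0, nv = min(R, nrow(omega), ncol(omega)))
    rank <- sum(s$d > 1e-12 * s$d[1])
    k <- min(R, rank)
    if (k > 0) W[, seq_len(k)] <- s$v[, seq_len(k), drop = FALSE]
  }
  W <- .fix_signs(W)
  beta <- lapply(seq_len(T_blocks), function(t) {
    W[((t - 1) * R + 1):(t * R), , drop = FALSE]
  })
  list(stacked = W, beta = beta)
}

# Internal: Moore-Penrose pseudo-inverse via SVD; singular values below
# 1e-10 x the largest are treated as zero (rank-deficient score matrices are
# expected, e.g. fewer surviving covariates than components).
.pinv <- function(m, tol = 1e-10) {
  m <- as.matrix(m)
  if (all(m == 0)) return(t(m))
  s <- svd(m)
  keep <- s$d > tol * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
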