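# Internal fitting core operating on already-standardized plain matrices.
# Kept free of S3 plumbing because the leave-one-out grid search calls it
# thousands of times.
.fit_core <- function(Xs, Ys, R, L0) {
  n <- nrow(Ys)
  q <- ncol(Ys)
  T_blocks <- length(Xs)
  p <- vapply(Xs, ncol, integer(1))

  cc <- lapply(Xs, function(x) crossprod(Ys, x) / (n - 1))
  col_max <- lapply(cc, function(m) apply(abs(m), 2, max))
  flat_max <- unlist(col_max, use.names = FALSE)

  empty <- function(lambda) {
    list(lambda = lambda,
         Ut = lapply(p, function(pt) matrix(0, pt, R)),
         beta = replicate(T_blocks, matrix(0, R, R), simplify = FALSE),
         C = matrix(0, R, q),
         B = lapply(p, function(pt) matrix(0, pt, q)),
         selected_cols = lapply(p, function(pt) integer(0)),
         selected_responses = rep(FALSE, q),
         intercept_only = TRUE)
  }
  if (all(flat_max == 0)) return(empty(0))

  candidates <- sort(unique(c(0, flat_max)))
  counts <- vapply(candidates, function(l) sum(flat_max > l), integer(1))
  lambda <- candidates[which(counts <= L0)[1]]
  if (sum(flat_max > lambda) == 0) return(empty(lambda))

  th <- lapply(cc, function(m) sign(m) * pmax(abs(m) - lambda, 0))
  sel_resp <- Reduce(`|`, lapply(th, function(m) rowSums(m != 0) > 0))

  Ut <- lapply(th, block_weights, R = R)
  Z <- do.call(cbind, Map(`%*%`, Xs, Ut))
  sw <- super_weights(Z, Ys, R)
  S <- Z %*% sw$stacked
  C <- .pinv(S) %*% Ys
  C[, !sel_resp] <- 0
  B <- Map(function(u, b) u %*% b %*% C, Ut, sw$beta)
  selected_cols <- Map(function(bt, cm) which(rowSums(bt != 0) > 0 & cm > lambda),
                       B, col_max)
  list(lambda = lambda, Ut = Ut, beta = sw$beta, C = C, B = B,
       selected_cols = selected_cols, selected_responses = sel_resp,
       intercept_only = FALSE)
}

#' Fit a multi-block data-driven sparse PLS model
#'
#' Pipeline: standardize all blocks and the response; compute per-block
#' cross-covariances \eqn{Y^\top X_t/(n-1)}; choose \eqn{\lambda} so that at
#' most `L0` covariate columns survive soft-thresholding (see
#' [select_lambda()]); take the top-`R` right singular vectors per block
#' ([block_weights()]); aggregate block scores with super-weights
#' ([super_weights()]); regress the standardized response on the `R`
#' super-components via Moore-Penrose pseudo-inverse (no matrix inversion;
#' rank-deficient score matrices are handled); assemble the per-block
#' regression matrices \eqn{B_t = U_t \beta_t C} so that
#' \eqn{Y \approx \sum_t X_t B_t}.
#'
#' Covariates zeroed by the threshold have exactly zero rows in \eqn{B_t};
#' responses whose rows of every thresholded cross-covariance are zero are
#' recorded as unselected and predicted by their training mean. If no
#' covariate survives at all, the model degenerates to intercept-only
#' (predicts training means) -- a valid model, not an error.
#'
#' @param data a [block_dataset()].
#' @param R number of components, a positive integer `<= q` (the model cannot
#'   carry more components than the response dimension).
#' @param L0 covariate budget: the maximum total number of covariate columns
#'   retained across all blocks.
#' @return an object of class `ddspls_model`.
#' @examples
#' spec <- synthetic_spec(n = 20, block_sizes = c(b1 = 5), q = 2, r_true = 1,
#'                        x_loadings = list(b1 = matrix(c(1, 1, 1, 0, 0), 5, 1)),
#'                        y_loadings = matrix(1, 2, 1),
#'                        noise_sd_x = 0, noise_sd_y = 0, seed = 7)
#' d <- generate_multiblock(spec)$data
#' m <- fit_ddspls(d, R = 1, L0 = 3)
#' m$selected_covariates
#' @export
fit_ddspls <- function(data, R, L0) {
  stopifnot(inherits(data, "block_dataset"))
  q <- ncol(data$response)
  if (!is.numeric(R) || length(R) != 1 || R < 1 || R != round(R) || R > q)
    stop_parameter(sprintf("'R' must be a positive integer <= q = %d", q))
  if (!is.numeric(L0) || length(L0) != 1 || L0 < 1 || L0 != round(L0))
    stop_parameter("'L0' must be a positive integer")

  std <- standardize(data)
  core <- .fit_core(std$data$blocks, std$data$response, R, L0)

  sel <- do.call(rbind, lapply(names(data$blocks), function(bn) {
    idx <- core$selected_cols[[bn]]
    if (!length(idx)) return(NULL)
    data.frame(block = bn, column = colnames(data$blocks[[bn]])[idx],
               stringsAsFactors = FALSE)
  }))
  if (is.null(sel)) sel <- data.frame(block = character(0), column = character(0))

  structure(
    list(
      R = R, L0 = L0, lambda = core$lambda,
      block_weights = core$Ut, super_weights = core$beta,
      component_regression = core$C, regression = core$B,
      selected_covariates = sel,
      selected_responses = colnames(data$response)[core$selected_responses],
      intercept_only = core$intercept_only,
      training_params = std$params,
      block_names = names(data$blocks),
      column_names = block_column_names(data),
      response_names = colnames(data$response),
      n = nrow(data$response)
    ),
    class = "ddspls_model"
  )
}

#' @export
print.ddspls_model <- function(x, ...) {
  cat(sprintf("ddspls_model: R = %d, L0 = %d, lambda = %.4g\n", x$R, x$L0, x$lambda))
  cat(sprintf("  selected covariates: %d / budget %d\n",
              nrow(x$selected_covariates), x$L0))
  cat("  selected responses:", if (length(x$selected_responses))
    paste(x$selected_responses, collapse = ", ") else "(none: intercept-only)", "\n")
  invisible(x)
}

#' Predict responses for new individuals
#'
#' New rows are standardized with the training parameters, pushed through
#' \eqn{\sum_t X_t B_t} and mapped back to original response units. Responses
#' with no contributing selected covariate are predicted as the constant
#' training mean.
#'
#' @param object a fitted [fit_ddspls()] model.
#' @param new_blocks a [block_dataset()] or named list of matrices with the
#'   training column structure.
#' @param ... unused.
#' @return matrix of predictions in original response units.
#' @export
predict.ddspls_model <- function(object, new_blocks, ...) {
  blocks <- if (inherits(new_blocks, "block_dataset")) new_blocks$blocks else new_blocks
  if (!setequal(names(blocks), object$block_names))
    stop_schema("new data blocks do not match the training blocks")
  pred_std <- NULL
  for (bn in object$block_names) {
    b <- as.matrix(blocks[[bn]])
    train_cols <- object$column_names[[bn]]
    if (!is.null(colnames(b))) {
      unknown <- setdiff(colnames(b), train_cols)
      if (length(unknown))
        stop_schema(sprintf("block '%s': unknown column(s) %s", bn,
                            paste(unknown, collapse = ", ")))
      if (!setequal(colnames(b), train_cols))
        stop_schema(sprintf("block '%s': missing training column(s)", bn))
      b <- b[, train_cols, drop = FALSE]
    } else if (ncol(b) != length(train_cols)) {
      stop_schema(sprintf("block '%s': expected %d columns, got %d", bn,
                          length(train_cols), ncol(b)))
    }
    pp <- object$training_params$blocks[[bn]]
    bs <- sweep(sweep(b, 2, pp$center, "-"), 2, pp$scale, "/")
    contrib <- bs %*% object$regression[[bn]]
    pred_std <- if (is.null(pred_std)) contrib else pred_std + contrib
  }
  out <- destandardize_predictions(pred_std, object$training_params)
  colnames(out) <- object$response_names
  out
}

#' First PLS component by NIPALS iteration
#'
#' Classical one-component (PLS2) NIPALS solving
#' \eqn{\arg\max_{\|u\|=\|v\|=1} (Yv)^\top (Xu)}; used in this package as an
#' independent oracle for the \eqn{\lambda = 0} single-block weight (the
#' dominant right singular vector of \eqn{Y^\top X}).
#'
#' @param X standardized `n x p` covariate matrix.
#' @param Y standardized `n x q` response matrix.
#' @param tol convergence tolerance on successive `u` change.
#' @param max_iter iteration cap.
#' @return list with unit-norm weights `u` (p), `v` (q) and scores `t = Xu`,
#'   `s = Yv`, plus the iteration count.
#' @export
nipals_first_component <- function(X, Y, tol = 1e-12, max_iter = 500) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y) || nrow(X) < 2)
    stop_schema("X and Y must share n >= 2 rows")
  M <- crossprod(Y, X)  # q x p
  if (all(M == 0)) stop_no_signal("Y'X is identically zero")
  u <- M[which.max(rowSums(M^2)), ]
  u <- u / sqrt(sum(u^2))
  v <- rep(1 / sqrt(ncol(Y)), ncol(Y))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    t_score <- X %*% u
    v <- crossprod(Y, t_score)
    v <- v / sqrt(sum(v^2))
    s_score <- Y %*% v
    u_new <- crossprod(X, s_score)
    u_new <- u_new / sqrt(sum(u_new^2))
    delta <- sqrt(sum((u_new - u)^2))
    u <- as.vector(u_new)
    if (delta < tol || iter >= max_iter) break
  }
  list(u = u, v = as.vector(v), t = as.vector(X %*% u),
       s = as.vector(Y %*% v), iterations = iter)
}
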