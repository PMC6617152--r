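#' Leave-one-out MSEP for one (R, L0) setting
#'
#' For each individual `i`, the whole pipeline (standardization, lambda
#' selection, SVD weights, regression) is refit on the `n - 1` remaining rows
#' and row `i` is predicted; anything less would leak the held-out row into
#' the selection. The squared errors are computed on the response scale
#' standardized with **full-sample** parameters, so that MSEP = 1 is the
#' mean-prediction reference level: values below 1 mean the cross-validated
#' model beats predicting the average, values above 1 mean it does worse.
#'
#' Rows are processed in a canonical order (sorted `row_ids`), which makes
#' the result exactly invariant to row permutations of the input.
#'
#' @param data a [block_dataset()] with `n >= 3`.
#' @param R,L0 model parameters (see [fit_ddspls()]).
#' @param return_predictions if `TRUE`, attach the matrix of LOO predictions
#'   (original units, rows in the canonical order) as attribute
#'   `"predictions"` together with `"observed"` and `"row_ids"`.
#' @return named numeric vector of `q` MSEP values (one per response).
#' @export
loo_msep <- function(data, R, L0, return_predictions = FALSE) {
  stopifnot(inherits(data, "block_dataset"))
  n <- nrow(data$response)
  if (n < 3) stop_degenerate("leave-one-out needs n >= 3")
  ord <- order(data$row_ids, method = "radix")
  X <- lapply(data$blocks, function(b) b[ord, , drop = FALSE])
  Y <- data$response[ord, , drop = FALSE]

  ref_center <- colMeans(Y)
  ref_scale <- apply(Y, 2, stats::sd)
  ref_scale[!is.finite(ref_scale) | ref_scale == 0] <- 1

  preds <- matrix(NA_real_, n, ncol(Y), dimnames = list(NULL, colnames(Y)))
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    Xs <- vector("list", length(X)); names(Xs) <- names(X)
    centers <- scales <- vector("list", length(X))
    for (t in seq_along(X)) {
      s <- .std_mat(X[[t]][keep, , drop = FALSE])
      Xs[[t]] <- s$mat; centers[[t]] <- s$center; scales[[t]] <- s$scale
    }
    sy <- .std_mat(Y[keep, , drop = FALSE])
    fit <- .fit_core(Xs, sy$mat, R, L0)
    pred_std <- rep(0, ncol(Y))
    for (t in seq_along(X)) {
      xnew <- (X[[t]][i, ] - centers[[t]]) / scales[[t]]
      pred_std <- pred_std + as.vector(xnew %*% fit$B[[t]])
    }
    preds[i, ] <- sy$center + sy$scale * pred_std
  }
  err <- sweep(Y - preds, 2, ref_scale, "/")
  msep <- colMeans(err^2)
  if (return_predictions) {
    attr(msep, "predictions") <- preds
    attr(msep, "observed") <- Y
    attr(msep, "row_ids") <- data$row_ids[ord]
  }
  msep
}

#' Grid search over (R, L0) by leave-one-out MSEP
#'
#' Evaluates [loo_msep()] at every grid point and records the full MSEP
#' surface (per response and averaged), for curve plots of MSEP against `L0`
#' with one line per `R`. Defaults: `R` from 1 to `q`, `L0` from 1 to 30.
#'
#' @param data a [block_dataset()].
#' @param R_values integer vector of component counts (`<= q`).
#' @param L0_values integer vector of covariate budgets.
#' @return object of class `cv_grid_result`: `grid` data frame (R, L0,
#'   per-response MSEP columns, `msep_mean`), `best` (list with R, L0), and
#'   `best_predictions` (LOO predictions of the best model, original units).
#' @export
grid_search <- function(data, R_values = NULL, L0_values = NULL) {
  stopifnot(inherits(data, "block_dataset"))
  q <- ncol(data$response)
  if (is.null(R_values)) R_values <- seq_len(q)
  if (is.null(L0_values)) L0_values <- seq_len(30)
  if (!length(R_values) || !length(L0_values))
    stop_parameter("empty parameter grid")
  if (max(R_values) > q)
    stop_parameter(sprintf("max(R_values) = %d exceeds q = %d", max(R_values), q))

  grid <- expand.grid(R = as.integer(R_values), L0 = as.integer(L0_values),
                      KEEP.OUT.ATTRS = FALSE)
  msep <- matrix(NA_real_, nrow(grid), q,
                 dimnames = list(NULL, colnames(data$response)))
  for (g in seq_len(nrow(grid)))
    msep[g, ] <- loo_msep(data, grid$R[g], grid$L0[g])
  surface <- cbind(grid, as.data.frame(msep), msep_mean = rowMeans(msep))

  res <- structure(list(grid = surface,
                        response_names = colnames(data$response),
                        best = NULL, best_predictions = NULL),
                   class = "cv_grid_result")
  res$best <- select_best(res)
  best_msep <- loo_msep(data, res$best$R, res$best$L0, return_predictions = TRUE)
  res$best_predictions <- attr(best_msep, "predictions")
  res$best_observed <- attr(best_msep, "observed")
  res$best_row_ids <- attr(best_msep, "row_ids")
  res
}

#' @export
print.cv_grid_result <- function(x, ...) {
  cat(sprintf("cv_grid_result: %d grid points, best (R = %d, L0 = %d), mean MSEP %.4f\n",
              nrow(x$grid), x$best$R, x$best$L0, x$best$msep_mean))
  invisible(x)
}

#' Select the best grid point
#'
#' Returns the (R, L0) minimizing the response-averaged MSEP. Ties (within
#' 1e-12) are broken by parsimony: smaller `L0` first, then smaller `R`.
#'
#' @param result a [grid_search()] result.
#' @return list with `R`, `L0` and `msep_mean`.
#' @export
select_best <- function(result) {
  stopifnot(inherits(result, "cv_grid_result"))
  g <- result$grid
  if (!nrow(g)) stop_parameter("empty grid result")
  best_val <- min(g$msep_mean)
  cand <- which(g$msep_mean <= best_val + 1e-12)
  cand <- cand[order(g$L0[cand], g$R[cand])]
  i <- cand[1]
  list(R = g$R[i], L0 = g$L0[i], msep_mean = g$msep_mean[i])
}

#' Export a cross-validation surface to CSV / JSON
#'
#' @param result a [grid_search()] result.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the result.
#' @export
write_cv_result <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "cv_grid_result"))
  long <- do.call(rbind, lapply(result$response_names, function(rn) {
    data.frame(R = result$grid$R, L0 = result$grid$L0, response = rn,
               msep = result$grid[[rn]])
  }))
  long <- rbind(long, data.frame(R = result$grid$R, L0 = result$grid$L0,
                                 response = "(mean)", msep = result$grid$msep_mean))
  if (!is.null(csv_path)) utils::write.csv(long, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(grid = result$grid, best = result$best),
                         json_path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(result)
}
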