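#' Standardize a multi-block dataset
#'
#' Centers every column of every block and of the response to mean zero and
#' scales it to unit sample standard deviation (denominator `n - 1`, matching
#' the `n - 1` of the cross-covariance matrices used by the model). The
#' response is standardized because the MSEP reference level of 1 (mean
#' prediction) is defined on that scale; covariates are standardized because
#' the soft-thresholding of the cross-covariance is scale-sensitive and
#' abundance units are heterogeneous across biomarkers.
#'
#' Constant columns are centered, their scale is recorded as 1 and they are
#' flagged; they are not an error (degenerate synthetic cases remain usable).
#'
#' @param data a [block_dataset()] with `n >= 2` rows.
#' @return list with elements `data` (the standardized [block_dataset()]) and
#'   `params` (a `standardization_params` object: per block and for the
#'   response, `center`, `scale` and logical `constant` vectors).
#' @examples
#' d <- block_dataset(list(b = matrix(1:9, 3, 3)), matrix(c(1, 2, 3), 3, 1))
#' s <- standardize(d)
#' colMeans(s$data$blocks$b)  # ~0
#' @export
standardize <- function(data) {
  stopifnot(inherits(data, "block_dataset"))
  std_one <- function(m) {
    center <- colMeans(m)
    centered <- sweep(m, 2, center, "-")
    sc <- apply(m, 2, stats::sd)
    constant <- !is.finite(sc) | sc == 0
    sc[constant] <- 1
    list(mat = sweep(centered, 2, sc, "/"),
         center = center, scale = sc, constant = constant)
  }
  bs <- lapply(data$blocks, std_one)
  ys <- std_one(data$response)
  params <- structure(
    list(
      blocks = lapply(bs, function(z) z[c("center", "scale", "constant")]),
      response = ys[c("center", "scale", "constant")]
    ),
    class = "standardization_params"
  )
  out <- block_dataset(lapply(bs, `[[`, "mat"), ys$mat, row_ids = data$row_ids)
  list(data = out, params = params)
}

#' Map standardized predictions back to original response units
#'
#' @param pred numeric matrix of predictions on the standardized response
#'   scale, `q` columns in response order.
#' @param params a `standardization_params` object from [standardize()].
#' @return matrix in original response units.
#' @export
destandardize_predictions <- function(pred, params) {
  stopifnot(inherits(params, "standardization_params"))
  pred <- as.matrix(pred)
  q <- length(params$response$center)
  if (ncol(pred) != q)
    stop_schema(sprintf("predictions have %d columns, expected %d responses",
                        ncol(pred), q))
  sweep(sweep(pred, 2, params$response$scale, "*"), 2, params$response$center, "+")
}

# Internal: standardize plain matrices with given (or freshly computed)
# center/scale. Used on the hot path (LOO folds) to avoid constructor overhead.
.std_mat <- function(m, center = NULL, scale = NULL) {
  if (is.null(center)) {
    center <- colMeans(m)
    scale <- apply(m, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  list(mat = sweep(sweep(m, 2, center, "-"), 2, scale, "/"),
       center = center, scale = scale)
}
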