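#' Coefficient of determination
#'
#' `1 - SSE/SST` of predictions against observations on the original
#' response scale. Can be negative for models worse than the mean; equals
#' squared Pearson correlation only when the predictions are an affine fit.
#'
#' @param observed,predicted numeric vectors of equal length (`n >= 2`).
#' @return scalar R-squared.
#' @examples
#' r_squared(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))  # 0.98
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop_schema("'observed' and 'predicted' must have equal length >= 2")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0)
    stop_degenerate("constant 'observed': R-squared is undefined")
  1 - sum((observed - predicted)^2) / sst
}

#' Selection report: which biomarkers predict which response, and how
#'
#' For each response, extracts the covariates with a non-zero row in the
#' corresponding column of the regression matrices \eqn{B_t}: block of
#' origin, biomarker name, coefficient on the standardized scale (comparable
#' across biomarkers), coefficient mapped back to original units, and sign.
#' Training predictions give per-response R-squared; when a cross-validation
#' result is supplied, a cross-validated R-squared (`1 - MSEP * n/(n-1)`,
#' from the LOO errors on the standardized scale) is reported separately so
#' the two are never conflated. Responses whose predictions are constant
#' (no contributing covariate) are flagged; their training R-squared is 0.
#'
#' The block-of-origin by response cross-table makes visible whether selected
#' biomarkers come from the muscle whose response they predict or from other
#' muscles.
#'
#' @param model a fitted [fit_ddspls()] model.
#' @param data the training [block_dataset()].
#' @param cv optional [grid_search()] result for the cross-validated metrics.
#' @return object of class `selection_report`: `coefficients` (long data
#'   frame), `response_summary` (R-squared, constant flag, per response),
#'   `cross_table` (selected-covariate counts, block x response), and the
#'   chosen `R`, `L0`, `lambda`.
#' @export
build_selection_report <- function(model, data, cv = NULL) {
  stopifnot(inherits(model, "ddspls_model"), inherits(data, "block_dataset"))
  pred <- predict(model, data)
  obs <- data$response

  coefs <- do.call(rbind, lapply(model$block_names, function(bn) {
    B <- model$regression[[bn]]
    sx <- model$training_params$blocks[[bn]]$scale
    sy <- model$training_params$response$scale
    do.call(rbind, lapply(seq_along(model$response_names), function(m) {
      rows <- which(B[, m] != 0)
      if (!length(rows)) return(NULL)
      data.frame(
        response = model$response_names[m],
        block = bn,
        biomarker = model$column_names[[bn]][rows],
        coefficient_std = B[rows, m],
        coefficient_raw = B[rows, m] * sy[m] / sx[rows],
        sign = ifelse(B[rows, m] > 0, "+", "-"),
        stringsAsFactors = FALSE
      )
    }))
  }))
  if (is.null(coefs))
    coefs <- data.frame(response = character(0), block = character(0),
                        biomarker = character(0), coefficient_std = numeric(0),
                        coefficient_raw = numeric(0), sign = character(0))

  constant <- apply(pred, 2, function(x) max(x) - min(x) == 0)
  r2 <- vapply(seq_len(ncol(obs)), function(m) {
    if (constant[m]) 0 else r_squared(obs[, m], pred[, m])
  }, numeric(1))
  summary <- data.frame(response = model$response_names, r_squared = r2,
                        constant_prediction = unname(constant),
                        n_selected = vapply(model$response_names, function(rn)
                          sum(coefs$response == rn), integer(1)))
  if (!is.null(cv)) {
    stopifnot(inherits(cv, "cv_grid_result"))
    i <- which(cv$grid$R == model$R & cv$grid$L0 == model$L0)
    if (length(i) == 1) {
      msep <- as.numeric(cv$grid[i, model$response_names])
      n <- model$n
      summary$msep_loo <- msep
      summary$r_squared_cv <- 1 - msep * n / (n - 1)
    }
  }

  cross <- table(factor(coefs$block, levels = model$block_names),
                 factor(coefs$response, levels = model$response_names))

  structure(
    list(coefficients = coefs, response_summary = summary,
         cross_table = cross,
         R = model$R, L0 = model$L0, lambda = model$lambda),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("selection_report (R = %d, L0 = %d, lambda = %.4g)\n",
              x$R, x$L0, x$lambda))
  for (rn in x$response_summary$response) {
    row <- x$response_summary[x$response_summary$response == rn, ]
    sel <- x$coefficients[x$coefficients$response == rn, ]
    if (nrow(sel) == 0) {
      cat(sprintf("  %s: mean prediction (no biomarker selected)\n", rn))
    } else {
      cat(sprintf("  %s (R2 = %.2f): %s\n", rn, row$r_squared,
                  paste(sprintf("%s/%s (%s)", sel$block, sel$biomarker, sel$sign),
                        collapse = ", ")))
    }
  }
  invisible(x)
}

#' Write a selection report to JSON
#' @param report a [build_selection_report()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  jsonlite::write_json(
    list(R = report$R, L0 = report$L0, lambda = report$lambda,
         coefficients = report$coefficients,
         response_summary = report$response_summary,
         cross_table = as.data.frame(report$cross_table,
                                     responseName = "n_selected")),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
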