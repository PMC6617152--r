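#' MSEP curves against the covariate budget
#'
#' One panel per response plus the response average; MSEP against `L0`, one
#' line per `R`. The dashed line at 1 is the mean-prediction reference.
#'
#' @param cv a [grid_search()] result.
#' @export
plot_msep_curves <- function(cv) {
  stopifnot(inherits(cv, "cv_grid_result"))
  panels <- c(cv$response_names, "(mean)")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(panels)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  Rs <- sort(unique(cv$grid$R))
  for (pn in panels) {
    vals <- if (pn == "(mean)") cv$grid$msep_mean else cv$grid[[pn]]
    graphics::plot(NA, xlim = range(cv$grid$L0), ylim = range(c(vals, 1)),
                   xlab = "L0 (covariate budget)", ylab = "LOO MSEP", main = pn)
    graphics::abline(h = 1, lty = 2, col = "grey50")
    for (k in seq_along(Rs)) {
      sel <- cv$grid$R == Rs[k]
      graphics::lines(cv$grid$L0[sel], vals[sel], col = k, lwd = 1.5)
      graphics::points(cv$grid$L0[sel], vals[sel], col = k, pch = 16, cex = 0.5)
    }
    graphics::legend("topright", legend = paste("R =", Rs), col = seq_along(Rs),
                     lwd = 1.5, bty = "n", cex = 0.8)
  }
  invisible(cv)
}

#' Predicted against observed responses
#'
#' One panel per response, LOO predictions of the best model against the
#' observed values. Responses with no selected covariates show the
#' characteristic horizontal alignment of mean predictions.
#'
#' @param cv a [grid_search()] result (its `best_predictions` are used).
#' @export
plot_predicted_observed <- function(cv) {
  stopifnot(inherits(cv, "cv_grid_result"))
  obs <- cv$best_observed; pred <- cv$best_predictions
  old <- graphics::par(mfrow = grDevices::n2mfrow(ncol(obs)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in seq_len(ncol(obs))) {
    rng <- range(c(obs[, m], pred[, m]))
    graphics::plot(obs[, m], pred[, m], xlim = rng, ylim = rng,
                   xlab = "observed", ylab = "predicted (LOO)",
                   main = colnames(obs)[m], pch = 16)
    graphics::abline(0, 1, lty = 2, col = "grey50")
  }
  invisible(cv)
}

#' Coefficient bars per response
#'
#' Standardized-scale coefficients of the selected biomarkers, one panel per
#' response with at least one selection.
#'
#' @param report a [build_selection_report()] result.
#' @export
plot_coefficients <- function(report) {
  stopifnot(inherits(report, "selection_report"))
  co <- report$coefficients
  responses <- unique(co$response)
  if (!length(responses)) {
    graphics::plot.new()
    graphics::title("no biomarker selected for any response")
    return(invisible(report))
  }
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(responses)),
                       mar = c(7, 4, 2, 1))
  on.exit(graphics::par(old))
  for (rn in responses) {
    sel <- co[co$response == rn, ]
    graphics::barplot(sel$coefficient_std,
                      names.arg = paste(sel$block, sel$biomarker, sep = "/"),
                      las = 2, cex.names = 0.7, main = rn,
                      ylab = "coefficient (standardized)",
                      col = ifelse(sel$coefficient_std > 0, "steelblue", "firebrick"))
    graphics::abline(h = 0)
  }
  invisible(report)
}
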