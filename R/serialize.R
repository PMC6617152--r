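#' Serialize a fitted model to JSON
#'
#' Writes every quantity needed to reproduce predictions exactly: `lambda`,
#' `R`, `L0`, the dense `Ut` / `beta_t` / `B_t` arrays, the component
#' regression matrix, selected sets and the training standardization
#' parameters, at full floating-point precision. [read_model_json()] restores
#' a model whose predictions are bit-identical to the original's.
#'
#' @param model a [fit_ddspls()] model.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "ddspls_model"))
  payload <- list(
    format = "blockpls_model",
    version = 1L,
    R = model$R, L0 = model$L0, lambda = model$lambda,
    n = model$n,
    block_names = model$block_names,
    column_names = model$column_names,
    response_names = model$response_names,
    block_weights = model$block_weights,
    super_weights = model$super_weights,
    component_regression = model$component_regression,
    regression = model$regression,
    selected_covariates = model$selected_covariates,
    selected_responses = model$selected_responses,
    intercept_only = model$intercept_only,
    training_params = list(
      blocks = model$training_params$blocks,
      response = model$training_params$response
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Load a model serialized by [write_model_json()]
#'
#' @param path JSON file path.
#' @return a `ddspls_model`.
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "blockpls_model"))
    stop_schema(sprintf("'%s' is not a blockpls model file", path))
  as_mat <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  }
  relist_params <- function(p, names_ref) {
    lapply(p, function(z) list(
      center = stats::setNames(as.numeric(z$center), names(z$center)),
      scale = stats::setNames(as.numeric(z$scale), names(z$scale)),
      constant = as.logical(z$constant)
    ))
  }
  bn <- j$block_names
  column_names <- j$column_names[bn]
  model <- list(
    R = as.integer(j$R), L0 = as.integer(j$L0), lambda = as.numeric(j$lambda),
    block_weights = lapply(j$block_weights[bn], as_mat),
    super_weights = lapply(j$super_weights, as_mat),
    component_regression = as_mat(j$component_regression),
    regression = lapply(j$regression[bn], as_mat),
    selected_covariates = as.data.frame(j$selected_covariates),
    selected_responses = as.character(unlist(j$selected_responses)),
    intercept_only = isTRUE(j$intercept_only),
    training_params = structure(
      list(blocks = relist_params(j$training_params$blocks[bn]),
           response = relist_params(list(j$training_params$response))[[1]]),
      class = "standardization_params"),
    block_names = bn,
    column_names = lapply(column_names, as.character),
    response_names = as.character(j$response_names),
    n = as.integer(j$n)
  )
  if (nrow(model$selected_covariates) == 0)
    model$selected_covariates <- data.frame(block = character(0), column = character(0))
  class(model) <- "ddspls_model"
  model
}
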