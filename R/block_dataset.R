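#' Multi-block dataset
#'
#' Container for a multi-block design: several covariate matrices ("blocks",
#' e.g. the biomarker abundances of one muscle each) observed on the same `n`
#' individuals, together with a response matrix (e.g. tenderness scores on a
#' 0--100 scale, one column per muscle).
#'
#' Invariants enforced at construction:
#' * every block and the response have exactly `n` rows, in identical order;
#' * `n >= 3`, every block has at least one column;
#' * column names unique within each block, response names unique;
#' * row identifiers unique;
#' * no missing values anywhere (no imputation in this package).
#'
#' @param blocks named list of numeric matrices (or data frames), one per
#'   block; all with `n` rows. Column names are the covariate (biomarker)
#'   names.
#' @param response numeric matrix (or data frame) with `n` rows and `q`
#'   columns; column names are the response names.
#' @param row_ids character vector of `n` unique individual identifiers. If
#'   `NULL`, taken from the rownames of `response`, else `"ind_1"..."ind_n"`.
#' @return an object of class `block_dataset` with elements `blocks`
#'   (named list of matrices), `response` (matrix) and `row_ids`.
#' @examples
#' x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "score"))
#' d <- block_dataset(list(muscle1 = x), y)
#' d
#' @export
block_dataset <- function(blocks, response, row_ids = NULL) {
  if (!is.list(blocks) || length(blocks) == 0)
    stop_schema("'blocks' must be a non-empty named list of matrices")
  if (is.null(names(blocks)) || any(!nzchar(names(blocks))) ||
      anyDuplicated(names(blocks)))
    stop_schema("block names must be present and unique")

  as_num_matrix <- function(x, what) {
    if (is.data.frame(x)) x <- as.matrix(x)
    if (!is.matrix(x) || !is.numeric(x))
      stop_schema(sprintf("%s must be a numeric matrix", what))
    x
  }
  response <- as_num_matrix(response, "'response'")
  blocks <- lapply(seq_along(blocks), function(t) {
    as_num_matrix(blocks[[t]], sprintf("block '%s'", names(blocks)[t]))
  }) |> stats::setNames(names(blocks))

  n <- nrow(response)
  if (n < 3) stop_schema(sprintf("need n >= 3 rows, got %d", n))
  for (t in seq_along(blocks)) {
    if (nrow(blocks[[t]]) != n)
      stop_alignment(sprintf("block '%s' has %d rows, response has %d",
                             names(blocks)[t], nrow(blocks[[t]]), n))
    if (ncol(blocks[[t]]) < 1)
      stop_schema(sprintf("block '%s' has no columns", names(blocks)[t]))
    if (is.null(colnames(blocks[[t]])))
      colnames(blocks[[t]]) <- paste0(names(blocks)[t], "_", seq_len(ncol(blocks[[t]])))
    if (anyDuplicated(colnames(blocks[[t]])))
      stop_schema(sprintf("duplicate column names within block '%s'", names(blocks)[t]))
  }
  if (is.null(colnames(response)))
    colnames(response) <- paste0("y", seq_len(ncol(response)))
  if (anyDuplicated(colnames(response)))
    stop_schema("duplicate response names")

  if (is.null(row_ids)) {
    row_ids <- rownames(response)
    if (is.null(row_ids)) row_ids <- paste0("ind_", seq_len(n))
  }
  row_ids <- as.character(row_ids)
  if (length(row_ids) != n) stop_schema("'row_ids' length must equal n")
  if (anyDuplicated(row_ids)) stop_alignment("duplicate row identifiers")

  if (anyNA(response) || any(vapply(blocks, anyNA, logical(1))))
    stop_missing("missing values are not supported (v1 does not impute)")

  for (t in seq_along(blocks)) rownames(blocks[[t]]) <- row_ids
  rownames(response) <- row_ids

  structure(
    list(blocks = blocks, response = response, row_ids = row_ids),
    class = "block_dataset"
  )
}

#' @export
print.block_dataset <- function(x, ...) {
  p <- vapply(x$blocks, ncol, integer(1))
  cat(sprintf("block_dataset: n = %d individuals, T = %d blocks, q = %d responses\n",
              nrow(x$response), length(x$blocks), ncol(x$response)))
  cat("  blocks:   ", paste(sprintf("%s (p=%d)", names(x$blocks), p), collapse = ", "), "\n")
  cat("  responses:", paste(colnames(x$response), collapse = ", "), "\n")
  invisible(x)
}

#' Per-block column names
#' @param data a [block_dataset()].
#' @return named list of character vectors, one per block.
#' @export
block_column_names <- function(data) {
  stopifnot(inherits(data, "block_dataset"))
  lapply(data$blocks, colnames)
}

#' Subset a block dataset by rows
#'
#' Keeps block structure and names; used internally by the leave-one-out
#' machinery.
#'
#' @param data a [block_dataset()].
#' @param idx integer or logical row index.
#' @return a [block_dataset()] with the selected rows.
#' @export
subset_rows <- function(data, idx) {
  stopifnot(inherits(data, "block_dataset"))
  block_dataset(
    blocks = lapply(data$blocks, function(b) b[idx, , drop = FALSE]),
    response = data$response[idx, , drop = FALSE],
    row_ids = data$row_ids[idx]
  )
}
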