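#' Read a multi-block dataset from CSV files
#'
#' Two layouts are supported:
#'
#' 1. **One file per block**: `data_paths` is a named list/vector with one CSV
#'    per block plus the response file named by `response`; every file has a
#'    header row and its first column is the individual ID.
#' 2. **Single wide CSV plus a block map**: `data_paths` is one path and
#'    `block_map` assigns every covariate column to exactly one named block,
#'    either as a named list `list(block = c("col", ...))` or a path to a YAML
#'    file with that structure; response columns are listed under the
#'    reserved name given by `response` (default `"response"`).
#'
#' Row order is taken from the response (file or wide CSV); covariate rows are
#' matched by ID. CSV dialect: comma separator, period decimal mark, UTF-8,
#' header mandatory, first column is the ID.
#'
#' @param data_paths named character vector of CSV paths (per-block layout) or
#'   a single path (wide layout).
#' @param block_map block-to-columns map for the wide layout (named list or
#'   YAML path); ignored in the per-block layout.
#' @param response name of the response entry in `data_paths` / `block_map`.
#' @return a validated [block_dataset()].
#' @export
read_block_dataset <- function(data_paths, block_map = NULL, response = "response") {
  if (length(data_paths) == 1 && !is.null(block_map)) {
    return(.read_wide(data_paths[[1]], block_map, response))
  }
  nm <- names(data_paths)
  if (is.null(nm) || !response %in% nm)
    stop_schema(sprintf("'data_paths' must be named and include '%s'", response))

  tabs <- lapply(data_paths, .read_id_csv)
  resp <- tabs[[response]]
  ids <- resp$ids
  blocks <- tabs[setdiff(nm, response)]
  aligned <- lapply(names(blocks), function(bn) {
    b <- blocks[[bn]]
    missing_ids <- setdiff(ids, b$ids)
    extra_ids <- setdiff(b$ids, ids)
    if (length(missing_ids) || length(extra_ids))
      stop_alignment(sprintf(
        "block '%s': IDs do not match the response file (missing: %s; unmatched: %s)",
        bn,
        if (length(missing_ids)) paste(missing_ids, collapse = ", ") else "none",
        if (length(extra_ids)) paste(extra_ids, collapse = ", ") else "none"))
    b$mat[match(ids, b$ids), , drop = FALSE]
  })
  names(aligned) <- names(blocks)
  block_dataset(aligned, resp$mat, row_ids = ids)
}

.read_id_csv <- function(path) {
  if (!file.exists(path))
    stop_schema(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop_schema(sprintf("'%s': need an ID column plus data columns", path))
  ids <- as.character(df[[1]])
  mat <- df[, -1, drop = FALSE]
  if (anyNA(mat) || any(!vapply(mat, is.numeric, logical(1))))
    stop_missing(sprintf("'%s': empty or non-numeric cells (v1 does not impute)", path))
  m <- as.matrix(mat)
  storage.mode(m) <- "double"
  list(ids = ids, mat = m)
}

.read_wide <- function(path, block_map, response) {
  if (is.character(block_map) && length(block_map) == 1)
    block_map <- yaml::read_yaml(block_map)
  if (!is.list(block_map) || !response %in% names(block_map))
    stop_schema(sprintf("block map must be a named list including '%s'", response))
  tab <- .read_id_csv(path)
  all_cols <- unlist(block_map, use.names = FALSE)
  missing_cols <- setdiff(all_cols, colnames(tab$mat))
  if (length(missing_cols))
    stop_schema(sprintf("block map names absent columns: %s",
                        paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(all_cols))
    stop_schema("block map assigns a column to more than one block")
  blocks <- lapply(block_map[setdiff(names(block_map), response)],
                   function(cols) tab$mat[, cols, drop = FALSE])
  block_dataset(blocks, tab$mat[, block_map[[response]], drop = FALSE],
                row_ids = tab$ids)
}

#' Write a multi-block dataset as CSV files
#'
#' Inverse of the per-block layout of [read_block_dataset()]: one CSV per
#' block plus `response.csv`, each with the ID as first column and columns in
#' the stored order, so a write/read round trip reproduces the dataset
#' exactly (including column ordering).
#'
#' @param data a [block_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written (suitable as
#'   `data_paths` for [read_block_dataset()]).
#' @export
write_block_dataset <- function(data, dir) {
  stopifnot(inherits(data, "block_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_one <- function(m, path) {
    df <- data.frame(id = data$row_ids, as.data.frame(m), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  paths <- c(
    stats::setNames(file.path(dir, paste0(names(data$blocks), ".csv")),
                    names(data$blocks)),
    response = file.path(dir, "response.csv")
  )
  for (bn in names(data$blocks)) write_one(data$blocks[[bn]], paths[[bn]])
  write_one(data$response, paths[["response"]])
  invisible(paths)
}
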