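#' Pearson correlation screen between biomarkers and responses
#'
#' Computes all covariate-by-response Pearson correlations with two-sided
#' p-values and applies the magnitude retention rule: a pair is retained iff
#' `|r| >= threshold` (inclusive; the conventional screen keeps coefficients
#' superior or equal to 0.55 / inferior or equal to -0.55). Pairs where the
#' biomarker block and the response share a name (the biomarker measured in
#' the muscle whose score it is screened against) are flagged `within_block`
#' so within-muscle and cross-muscle screens can be reported separately.
#'
#' The magnitude rule and the p-values answer different questions and are
#' kept separate: retention is decided by `|r|` alone, p-values are reported
#' alongside.
#'
#' @param data a [block_dataset()] with `n >= 3`.
#' @param threshold retention threshold in (0, 1]; default 0.55.
#' @return object of class `correlation_screen`: `table` (long data frame
#'   with block, biomarker, response, r, p, within_block, retained),
#'   `r_matrix` (covariates x responses), `threshold`, `n`. Zero-variance
#'   columns yield `NA` correlations, excluded from retention.
#' @export
pearson_screen <- function(data, threshold = 0.55) {
  stopifnot(inherits(data, "block_dataset"))
  n <- nrow(data$response)
  if (n < 3) stop_degenerate("need n >= 3 for a correlation screen")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop_parameter("'threshold' must be in (0, 1]")

  xall <- do.call(cbind, data$blocks)
  block_of <- rep(names(data$blocks), vapply(data$blocks, ncol, integer(1)))
  biomarker <- unlist(lapply(data$blocks, colnames), use.names = FALSE)

  sx <- apply(xall, 2, stats::sd)
  sy <- apply(data$response, 2, stats::sd)
  r <- suppressWarnings(stats::cor(xall, data$response))
  r[sx == 0 | !is.finite(sx), ] <- NA_real_
  r[, sy == 0 | !is.finite(sy)] <- NA_real_
  rownames(r) <- paste(block_of, biomarker, sep = ".")

  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)

  tab <- data.frame(
    block = rep(block_of, times = ncol(r)),
    biomarker = rep(biomarker, times = ncol(r)),
    response = rep(colnames(data$response), each = nrow(r)),
    r = as.vector(r),
    p = as.vector(p),
    stringsAsFactors = FALSE
  )
  tab$within_block <- tab$block == tab$response
  tab$retained <- !is.na(tab$r) & abs(tab$r) >= threshold

  structure(list(table = tab, r_matrix = r, threshold = threshold, n = n),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("correlation_screen: %d pairs, threshold |r| >= %.2f, %d retained\n",
              nrow(x$table), x$threshold, sum(x$table$retained)))
  invisible(x)
}

#' Write a correlation screen to CSV
#'
#' Long format (block, biomarker, response, r, p, within_block, retained);
#' optionally also the covariates-by-responses matrix layout.
#'
#' @param screen a [pearson_screen()] result.
#' @param csv_path long-format output path.
#' @param matrix_path optional matrix-layout output path.
#' @return invisibly, the screen.
#' @export
write_screen_csv <- function(screen, csv_path, matrix_path = NULL) {
  stopifnot(inherits(screen, "correlation_screen"))
  utils::write.csv(screen$table, csv_path, row.names = FALSE)
  if (!is.null(matrix_path))
    utils::write.csv(data.frame(covariate = rownames(screen$r_matrix),
                                screen$r_matrix, check.names = FALSE),
                     matrix_path, row.names = FALSE)
  invisible(screen)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA across groups (e.g. one biomarker's
#' abundance across muscles), reporting the F statistic, its p-value and the
#' group means.
#'
#' @param values numeric vector of measurements.
#' @param groups group labels (coerced to factor), same length as `values`.
#' @return list with `F`, `p`, `df` (numerator, denominator) and
#'   `group_means` (named).
#' @export
anova_one_way <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups))
    stop_schema("'values' and 'groups' lengths differ")
  if (anyNA(values)) stop_missing("missing values in 'values'")
  counts <- table(groups)
  if (nlevels(groups) < 2)
    stop_degenerate("need at least 2 groups")
  if (any(counts < 2))
    stop_degenerate("need at least 2 observations per group")
  k <- nlevels(groups)
  N <- length(values)
  means <- tapply(values, groups, mean)
  ssw <- sum((values - means[groups])^2)
  if (ssw == 0)
    stop_degenerate("zero within-group variance: F is undefined")
  ssb <- sum(counts * (means - mean(values))^2)
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fstat,
       p = stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE),
       df = c(k - 1, N - k),
       group_means = means)
}
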