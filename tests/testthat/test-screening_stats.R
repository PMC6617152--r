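test_that("pearson_screen computes r, p and the inclusive retention rule", {
  set.seed(1)
  n <- 12
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("m1", "m2", "m3")))
  y <- cbind(GB = x[, 1], SM = rnorm(n))
  d <- block_dataset(list(GB = x), y)
  sc <- pearson_screen(d)
  tab <- sc$table
  self <- tab[tab$biomarker == "m1" & tab$response == "GB", ]
  expect_equal(self$r, 1.0)
  expect_true(self$retained)
  expect_true(all(tab$within_block[tab$block == "GB" & tab$response == "GB"]))
  expect_false(any(tab$within_block[tab$response == "SM"]))
  # p-values match the classical t transform used by cor.test
  ct <- cor.test(x[, 2], y[, "SM"])
  row <- tab[tab$biomarker == "m2" & tab$response == "SM", ]
  expect_equal(row$p, ct$p.value, tolerance = 1e-12)
  # retained set is exactly reproducible from the matrix and threshold
  expect_equal(sum(tab$retained),
               sum(abs(sc$r_matrix) >= sc$threshold, na.rm = TRUE))
})

test_that("retention boundary is inclusive at exact threshold equality", {
  # u, v exactly orthogonal in floating point
  u <- c(0.5, 0.5, -0.5, -0.5)
  v <- c(0.5, -0.5, 0.5, -0.5)
  y <- 0.55 * u + sqrt(1 - 0.55^2) * v
  r_actual <- cor(u, y)
  d <- block_dataset(list(b = matrix(u, 4, 1, dimnames = list(NULL, "x"))),
                     matrix(y, 4, 1, dimnames = list(NULL, "score")))
  expect_true(pearson_screen(d, threshold = r_actual)$table$retained)
  up <- r_actual * (1 + 1e-9)
  expect_false(pearson_screen(d, threshold = up)$table$retained)
})

test_that("screen is invariant to affine rescaling of columns", {
  d <- random_dataset(n = 10, p = c(a = 4), q = 2, seed = 5)
  s1 <- pearson_screen(d)
  d2 <- d
  d2$blocks$a[, 2] <- 1000 * d2$blocks$a[, 2] - 37
  d2$response[, 1] <- 0.01 * d2$response[, 1] + 5
  s2 <- pearson_screen(d2)
  expect_lt(max(abs(s1$r_matrix - s2$r_matrix)), 1e-12)
})

test_that("zero-variance columns yield NA correlations excluded from retention", {
  n <- 8
  set.seed(2)
  d <- block_dataset(
    list(b = cbind(flat = rep(3, n), ok = rnorm(n))),
    matrix(rnorm(n), n, 1, dimnames = list(NULL, "y"))
  )
  sc <- pearson_screen(d)
  flat_rows <- sc$table[sc$table$biomarker == "flat", ]
  expect_true(all(is.na(flat_rows$r)))
  expect_false(any(flat_rows$retained))
})

test_that("null retained fraction matches the Pearson null tail at n = 10", {
  n <- 10
  thr <- 0.55
  t_thr <- thr * sqrt((n - 2) / (1 - thr^2))
  p_null <- 2 * pt(-t_thr, df = n - 2)  # closed-form null tail oracle
  hits <- 0L; total <- 0L
  for (s in 1:1000) {
    d <- random_dataset(n = n, p = c(b = 5), q = 2, seed = 20000 + s)
    sc <- pearson_screen(d, threshold = thr)
    hits <- hits + sum(sc$table$retained)
    total <- total + nrow(sc$table)
  }
  expect_lt(abs(hits / total - p_null), 0.015)
})

test_that("anova_one_way matches the classical equal-variance oracle", {
  set.seed(4)
  for (k in 1:20) {
    g <- factor(rep(letters[1:3], times = c(5, 7, 6)))
    v <- rnorm(length(g), mean = as.integer(g) * (k %% 3), sd = 1.5)
    mine <- anova_one_way(v, g)
    ref <- oneway.test(v ~ g, var.equal = TRUE)
    expect_equal(mine$F, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(unname(mine$group_means), unname(tapply(v, g, mean)))
  }
})

test_that("anova_one_way null p-values are uniform", {
  set.seed(5)
  ps <- vapply(1:500, function(k) {
    g <- rep(letters[1:3], each = 5)
    anova_one_way(rnorm(15, mean = 10), g)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("anova_one_way detects a large planted shift", {
  set.seed(6)
  g <- rep(c("a", "b"), each = 8)
  v <- rnorm(16, mean = ifelse(g == "a", 0, 5), sd = 1)
  expect_lt(anova_one_way(v, g)$p, 0.001)
})

test_that("anova_one_way rejects degenerate inputs", {
  expect_error(anova_one_way(rnorm(5), rep("a", 5)),
               class = "blockpls_degenerate_error")
  expect_error(anova_one_way(rnorm(4), c("a", "a", "a", "b")),
               class = "blockpls_degenerate_error")
  expect_error(anova_one_way(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3)),
               class = "blockpls_degenerate_error")
})

test_that("screen CSV export round-trips the long table", {
  d <- random_dataset(n = 10, p = c(a = 3, b = 2), q = 2, seed = 8)
  sc <- pearson_screen(d)
  csvp <- withr::local_tempfile(fileext = ".csv")
  matp <- withr::local_tempfile(fileext = ".csv")
  write_screen_csv(sc, csvp, matp)
  back <- read.csv(csvp)
  expect_equal(nrow(back), nrow(sc$table))
  expect_equal(back$r, sc$table$r, tolerance = 1e-12)
  m <- read.csv(matp, check.names = FALSE)
  expect_equal(ncol(m), 1 + ncol(d$response))
})
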