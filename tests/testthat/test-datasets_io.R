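test_that("block_dataset enforces its invariants", {
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- matrix(rnorm(20), 10, 2)
  d <- block_dataset(list(m = x), y)
  expect_s3_class(d, "block_dataset")
  expect_equal(colnames(d$blocks$m), c("a", "b", "c"))

  expect_error(block_dataset(list(m = x[1:9, ]), y),
               class = "blockpls_alignment_error")
  xd <- x; colnames(xd) <- c("a", "a", "c")
  expect_error(block_dataset(list(m = xd), y), class = "blockpls_schema_error")
  xn <- x; xn[2, 2] <- NA
  expect_error(block_dataset(list(m = xn), y),
               class = "blockpls_missing_data_error")
  expect_error(block_dataset(list(m = x[1:2, ]), y[1:2, , drop = FALSE]),
               class = "blockpls_schema_error")
  expect_error(block_dataset(list(m = x), y, row_ids = rep("i1", 10)),
               class = "blockpls_alignment_error")
})

test_that("per-block CSV round trip preserves values, names and order", {
  d <- random_dataset(n = 10, p = c(gb = 5, tb = 4), q = 3, seed = 11)
  dir <- withr::local_tempdir()
  paths <- write_block_dataset(d, dir)
  d2 <- read_block_dataset(paths)
  expect_equal(d2$blocks, d$blocks)
  expect_equal(d2$response, d$response)
  expect_equal(d2$row_ids, d$row_ids)
})

test_that("covariate rows are matched to the response by ID", {
  d <- random_dataset(n = 8, p = c(a = 3), q = 1, seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_block_dataset(d, dir)
  # shuffle the block file rows; read must realign them by ID
  tab <- read.csv(paths[["a"]], check.names = FALSE)
  write.csv(tab[sample(nrow(tab)), ], paths[["a"]], row.names = FALSE)
  d2 <- read_block_dataset(paths)
  expect_equal(d2$blocks$a, d$blocks$a)

  # an ID missing from a block file is an alignment error naming the row
  write.csv(tab[-3, ], paths[["a"]], row.names = FALSE)
  err <- expect_error(read_block_dataset(paths),
                      class = "blockpls_alignment_error")
  expect_match(conditionMessage(err), d$row_ids[3], fixed = TRUE)
})

test_that("wide CSV plus block map reads correctly, from list or YAML", {
  d <- random_dataset(n = 6, p = c(a = 2, b = 3), q = 2, seed = 3)
  dir <- withr::local_tempdir()
  wide <- data.frame(id = d$row_ids, d$blocks$a, d$blocks$b, d$response,
                     check.names = FALSE)
  wide_path <- file.path(dir, "wide.csv")
  write.csv(wide, wide_path, row.names = FALSE)
  bm <- list(a = colnames(d$blocks$a), b = colnames(d$blocks$b),
             response = colnames(d$response))
  d2 <- read_block_dataset(wide_path, block_map = bm)
  expect_equal(d2$blocks, d$blocks)

  ymap <- file.path(dir, "map.yaml")
  yaml::write_yaml(bm, ymap)
  d3 <- read_block_dataset(wide_path, block_map = ymap)
  expect_equal(d3$response, d$response)

  bm_bad <- bm; bm_bad$b <- c(bm$b, bm$a[1])  # column in two blocks
  expect_error(read_block_dataset(wide_path, block_map = bm_bad),
               class = "blockpls_schema_error")
})

test_that("empty cells are a missing-data error", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "resp.csv")
  writeLines(c("id,y1", "i1,1.0", "i2,", "i3,3.0"), p)
  q <- file.path(dir, "a.csv")
  writeLines(c("id,x1", "i1,1.0", "i2,2.0", "i3,3.0"), q)
  expect_error(read_block_dataset(c(a = q, response = p)),
               class = "blockpls_missing_data_error")
})

test_that("standardize centers and scales with denominator n-1", {
  d <- block_dataset(
    list(b = cbind(v = c(1, 2, 3), k = c(5, 5, 5))),
    matrix(c(10, 20, 60), 3, 1, dimnames = list(NULL, "y"))
  )
  s <- standardize(d)
  expect_equal(s$data$blocks$b[, "v"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(s$data$blocks$b[, "k"], c(0, 0, 0), ignore_attr = TRUE)
  expect_true(s$params$blocks$b$constant[["k"]])
  expect_false(s$params$blocks$b$constant[["v"]])
  expect_equal(s$params$blocks$b$scale[["k"]], 1)

  big <- random_dataset(n = 15, p = c(a = 6, b = 2), q = 3, seed = 9)
  sb <- standardize(big)
  for (bn in names(sb$data$blocks)) {
    expect_lt(max(abs(colMeans(sb$data$blocks[[bn]]))), 1e-12)
    expect_equal(apply(sb$data$blocks[[bn]], 2, sd), rep(1, ncol(sb$data$blocks[[bn]])),
                 ignore_attr = TRUE)
  }
})

test_that("standardize / destandardize round-trips within 1e-10", {
  for (seed in 1:5) {
    d <- random_dataset(n = 12, p = c(a = 5, b = 3), q = 4, seed = seed)
    s <- standardize(d)
    expect_lt(max(abs(destandardize_predictions(s$data$response, s$params) -
                        d$response)), 1e-10)
    for (bn in names(d$blocks)) {
      pp <- s$params$blocks[[bn]]
      back <- sweep(sweep(s$data$blocks[[bn]], 2, pp$scale, "*"), 2, pp$center, "+")
      expect_lt(max(abs(back - d$blocks[[bn]])), 1e-10)
    }
  }
})

test_that("destandardize_predictions handles degenerate shapes", {
  d <- random_dataset(n = 10, p = c(a = 2), q = 3, seed = 4)
  s <- standardize(d)
  # zero predictions map to the training means
  z <- destandardize_predictions(matrix(0, 10, 3), s$params)
  expect_equal(z, matrix(colMeans(d$response), 10, 3, byrow = TRUE),
               ignore_attr = TRUE)
  expect_error(destandardize_predictions(matrix(0, 10, 2), s$params),
               class = "blockpls_schema_error")
})
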