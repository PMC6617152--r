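test_that("soft_threshold follows the closed form and rejects bad lambda", {
  x <- matrix(c(-0.8, 0.5, 0, 2), 2, 2)
  expect_equal(soft_threshold(x, 0), x)
  expect_equal(soft_threshold(0.5, 1.0), 0)
  expect_equal(soft_threshold(-0.8, 0.3), -0.5)
  expect_error(soft_threshold(x, -0.1), class = "blockpls_parameter_error")
})

test_that("cross_covariance yields correlations on standardized data", {
  set.seed(1)
  n <- 20
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- cbind(y1 = x[, 2], y2 = rnorm(n))  # y1 duplicates covariate "b"
  d <- standardize(block_dataset(list(blk = x), y))$data
  cc <- cross_covariance(d)
  expect_equal(dim(cc$blocks$blk), c(2, 3))
  expect_equal(cc$blocks$blk["y1", "b"], 1.0)
  expect_equal(unname(cc$blocks$blk), unname(cor(y, x)), tolerance = 1e-12)
})

test_that("cross_covariance of independent noise concentrates near zero", {
  set.seed(42)
  n <- 1000
  d <- standardize(block_dataset(
    list(b = matrix(rnorm(n * 30), n, 30)),
    matrix(rnorm(n * 3), n, 3)))$data
  cc <- cross_covariance(d)
  expect_gt(mean(abs(cc$blocks$b) < 0.15), 0.99)
})

test_that("select_lambda reproduces the worked examples", {
  cc <- fake_cc(rbind(c(0.9, 0.5, 0.1)))
  s <- select_lambda(cc, 2)
  expect_equal(s$lambda, 0.1)
  expect_equal(s$selected$b1, c(1, 2))
  expect_equal(select_lambda(cc, 3)$lambda, 0)
  # ties make exactly L0 = 1 unattainable: lambda jumps past both tied columns
  cc2 <- fake_cc(rbind(c(0.6, 0.6, 0.2)))
  s2 <- select_lambda(cc2, 1)
  expect_equal(s2$lambda, 0.6)
  expect_equal(s2$n_selected, 0)
  expect_error(select_lambda(fake_cc(matrix(0, 2, 3)), 1),
               class = "blockpls_no_signal_error")
})

test_that("surviving-column count is non-increasing in lambda", {
  set.seed(7)
  for (k in 1:20) {
    cc <- fake_cc(matrix(rnorm(6), 2, 3), matrix(rnorm(8), 2, 4))
    cand <- sort(unique(c(0, unlist(cc$col_max))))
    counts <- vapply(cand, function(l) {
      sum(vapply(cc$blocks, function(m) {
        th <- soft_threshold(m, l)
        sum(colSums(th != 0) > 0)
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("block_weights: rank-1, zero, and orthonormal cases", {
  a <- c(2, -1); b <- c(3, 0, 4)
  U <- block_weights(a %*% t(b), R = 2)
  expect_equal(abs(U[, 1]), b / 5, tolerance = 1e-12)
  expect_equal(U[, 2], rep(0, 3))

  expect_equal(block_weights(matrix(0, 2, 4), R = 1), matrix(0, 4, 1),
               ignore_attr = TRUE)

  set.seed(3)
  m <- matrix(rnorm(15), 3, 5)
  U <- block_weights(m, R = 2)
  expect_lt(max(abs(crossprod(U) - diag(2))), 1e-10)
  expect_error(block_weights(m, R = 4), class = "blockpls_parameter_error")
})

test_that("block_weights zeroes rows of thresholded-out covariates exactly", {
  m <- rbind(c(0.5, 0, 0.2), c(0.1, 0, -0.3))
  U <- block_weights(m, R = 2)
  expect_identical(U[2, ], c(0, 0))
})

test_that("super_weights slices, shapes and degenerate cases", {
  set.seed(8)
  n <- 30
  # T = 1 with scores already maximally covariant with Y: responses
  # proportional to the two score axes give a diagonal cross-covariance with
  # distinct entries, so beta_1 is the identity up to sign
  Q <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  Z <- Q %*% diag(c(3, 1))
  Ydiag <- Q %*% diag(c(2, 1))
  sw2 <- super_weights(Z, Ydiag, R = 2)
  expect_equal(dim(sw2$stacked), c(2, 2))
  expect_equal(abs(sw2$beta[[1]]), diag(2), tolerance = 1e-10)
  Y <- matrix(rnorm(n * 2), n, 2)

  # zero scores (nothing survived) give zero super-weights
  sw3 <- super_weights(matrix(0, n, 4), Y, R = 2)
  expect_equal(sw3$stacked, matrix(0, 4, 2))
  expect_length(sw3$beta, 2)

  # super-component count is R regardless of T
  Z6 <- matrix(rnorm(n * 6), n, 6)  # T = 3 blocks at R = 2
  sw4 <- super_weights(Z6, Y, R = 2)
  expect_length(sw4$beta, 3)
  expect_equal(ncol(Z6 %*% sw4$stacked), 2)
  expect_error(super_weights(Z6[1:10, ], Y, R = 2),
               class = "blockpls_schema_error")
})

test_that("noiseless rank-1 fit recovers the exact support", {
  for (s in 1:5) {
    g <- generate_multiblock(rank1_spec(n = 20, noise = 0, seed = s))
    m <- fit_ddspls(g$data, R = 1, L0 = 3)
    expect_setequal(m$selected_covariates$column, g$truth$active$column)
    expect_lt(max(abs(predict(m, g$data) - g$data$response)), 1e-8)
  }
})

test_that("all-tied-at-zero covariates degenerate to an intercept-only model", {
  n <- 10
  d <- block_dataset(
    list(b = matrix(5, n, 3, dimnames = list(NULL, c("c1", "c2", "c3")))),
    matrix(rnorm(n * 2), n, 2)
  )
  m <- fit_ddspls(d, R = 1, L0 = 1)
  expect_true(m$intercept_only)
  expect_equal(nrow(m$selected_covariates), 0)
  p <- predict(m, d)
  expect_equal(p, matrix(colMeans(d$response), n, 2, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("budget and rank bounds hold on random fits", {
  for (s in 1:10) {
    d <- random_dataset(n = 12, p = c(a = 6, b = 5), q = 3, seed = 100 + s)
    L0 <- 1 + (s %% 5)
    m <- fit_ddspls(d, R = min(3, 1 + s %% 3), L0 = L0)
    expect_lte(nrow(m$selected_covariates), L0)
    # non-zero weight columns never exceed q
    for (U in m$block_weights) {
      nonzero <- sum(colSums(U != 0) > 0)
      expect_lte(nonzero, ncol(d$response))
    }
  }
  d <- random_dataset(seed = 1)
  expect_error(fit_ddspls(d, R = 5, L0 = 2), class = "blockpls_parameter_error")
  expect_error(fit_ddspls(d, R = 1, L0 = 0), class = "blockpls_parameter_error")
})

test_that("prediction checks its column structure", {
  d <- random_dataset(n = 10, p = c(a = 4, b = 3), q = 2, seed = 6)
  m <- fit_ddspls(d, R = 1, L0 = 3)
  bad <- d$blocks
  colnames(bad$a)[2] <- "unknown_marker"
  expect_error(predict(m, bad), class = "blockpls_schema_error")
  expect_error(predict(m, d$blocks["a"]), class = "blockpls_schema_error")
  # column order within a block does not matter when names are present
  shuffled <- d$blocks
  shuffled$a <- shuffled$a[, c(3, 1, 4, 2)]
  expect_equal(predict(m, shuffled), predict(m, d$blocks))
})

test_that("NIPALS solves the one-hot case and keeps unit norms", {
  # orthogonal-polynomial design: columns are centered and exactly
  # orthogonal, so the cross-covariance with Y = X[,3] is one-hot
  X <- unclass(poly(1:25, 5)) * sqrt(24)
  Y <- X[, 3, drop = FALSE]
  ni <- nipals_first_component(X, Y)
  expect_equal(abs(ni$u[3]), 1, tolerance = 1e-8)
  expect_lt(max(abs(ni$u[-3])), 1e-6)
  expect_equal(sum(ni$u^2), 1, tolerance = 1e-12)
  expect_equal(sum(ni$v^2), 1, tolerance = 1e-12)
  expect_error(nipals_first_component(X, matrix(0, 25, 2) * X[, 1:2]),
               class = "blockpls_no_signal_error")
})

test_that("NIPALS agrees with the SVD oracle on random instances", {
  set.seed(11)
  for (k in 1:20) {
    X <- scale(matrix(rnorm(30 * 8), 30, 8))
    Y <- scale(matrix(rnorm(30 * 3), 30, 3))
    ni <- nipals_first_component(X, Y)
    sv <- svd(crossprod(Y, X))$v[, 1]
    expect_gte(abs(sum(ni$u * sv)), 1 - 1e-8)
  }
})

test_that("ddsPLS weight at lambda = 0, T = 1, R = 1 equals the NIPALS u", {
  set.seed(12)
  for (k in 1:10) {
    n <- 20
    x <- matrix(rnorm(n * 6), n, 6)
    y <- matrix(rnorm(n * 2), n, 2)
    d <- block_dataset(list(b = x), y)
    m <- fit_ddspls(d, R = 1, L0 = 6)   # budget >= p forces lambda = 0
    expect_equal(m$lambda, 0)
    s <- standardize(d)$data
    ni <- nipals_first_component(s$blocks$b, s$response)
    u_fit <- m$block_weights$b[, 1]
    expect_gte(abs(sum(u_fit * ni$u)), 1 - 1e-8)
  }
})

test_that("model JSON round trip reproduces predictions bit-for-bit", {
  g <- generate_multiblock(study_preset(seed = 5))
  m <- fit_ddspls(g$data, R = 2, L0 = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_identical(predict(m2, g$data), predict(m, g$data))
  expect_equal(m2$lambda, m$lambda)
  expect_equal(m2$selected_covariates, m$selected_covariates)
})
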