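# Shared fixtures: everything is generated in code at test time.

# Plain random dataset with no planted structure.
random_dataset <- function(n = 10, p = c(a = 4, b = 3), q = 2, seed = 1) {
  set.seed(seed)
  blocks <- lapply(p, function(pt) {
    matrix(rnorm(n * pt), n, pt)
  })
  for (bn in names(blocks))
    colnames(blocks[[bn]]) <- paste0(bn, seq_len(ncol(blocks[[bn]])))
  y <- matrix(rnorm(n * q), n, q, dimnames = list(NULL, paste0("y", seq_len(q))))
  block_dataset(blocks, y)
}

# Rank-1 planted spec: 3 active columns in block 1 of 2, driving both of two
# responses; used by recovery tests.
rank1_spec <- function(n = 20, noise = 0, seed = 1, p = 8,
                       active = c(1, 3, 5), signs = c(1, -1, 1)) {
  A <- matrix(0, p, 1)
  A[active, 1] <- signs
  synthetic_spec(
    n = n, block_sizes = c(b1 = p, b2 = p), q = 2, r_true = 1,
    x_loadings = list(b1 = A, b2 = matrix(0, p, 1)),
    y_loadings = matrix(c(1, -1), 2, 1),
    noise_sd_x = noise, noise_sd_y = noise, seed = seed
  )
}

# Fake cross-covariance object with prescribed entries, for threshold tests.
fake_cc <- function(...) {
  blocks <- lapply(list(...), as.matrix)
  names(blocks) <- paste0("b", seq_along(blocks))
  structure(list(blocks = blocks,
                 col_max = lapply(blocks, function(m) apply(abs(m), 2, max))),
            class = "cross_covariance")
}

# Independent enumeration oracle for lambda selection: scan candidates over
# all distinct absolute entries (plus midpoints and 0), evaluate survival by
# actually soft-thresholding, take the smallest accepted candidate.
oracle_lambda <- function(cc, L0) {
  entries <- sort(unique(abs(unlist(lapply(cc$blocks, as.vector)))))
  mids <- (entries[-1] + entries[-length(entries)]) / 2
  candidates <- sort(unique(c(0, entries, mids)))
  count_at <- function(l) {
    sum(vapply(cc$blocks, function(m) {
      th <- sign(m) * pmax(abs(m) - l, 0)
      sum(colSums(th != 0) > 0)
    }, numeric(1)))
  }
  for (l in candidates) {
    if (count_at(l) <= L0) {
      surv <- lapply(cc$blocks, function(m) {
        th <- sign(m) * pmax(abs(m) - l, 0)
        which(colSums(th != 0) > 0)
      })
      return(list(lambda = l, selected = surv, n_selected = count_at(l)))
    }
  }
  stop("oracle: no candidate accepted")
}
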