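#' Specification for a synthetic multi-block dataset
#'
#' Describes a sparse low-rank latent-factor world: `r_true` independent
#' standard-normal factor scores drive a small set of active covariate
#' columns (fixed loading magnitudes with stated signs, so true coefficient
#' signs are well defined) and a subset of the responses; all remaining
#' covariates are pure noise. Additive noise is i.i.d. Gaussian -- the
#' implicit assumption of covariance-based PLS. Responses are affinely mapped
#' onto a 0--100-like scale.
#'
#' @param n number of individuals.
#' @param block_sizes named integer vector of per-block column counts.
#' @param q number of responses.
#' @param r_true number of latent factors (`>= 1`).
#' @param x_loadings named list (one entry per block) of `p_t x r_true`
#'   loading matrices; non-zero rows are the active covariates (the support).
#' @param y_loadings `q x r_true` response loading matrix; all-zero rows are
#'   signal-free responses.
#' @param noise_sd_x,noise_sd_y standard deviations (`>= 0`) of the additive
#'   Gaussian noise on covariates and (standardized-scale) responses.
#' @param response_center,response_scale affine map from the standardized
#'   latent response scale to reported units (defaults 45 and 8: tenderness
#'   panel scores cluster in the 30--60 range of the 0--100 scale with an
#'   among-animal spread of roughly 6--8 points).
#' @param column_names optional named list of per-block column name vectors.
#' @param response_names optional response names.
#' @param seed integer seed; identical specs (including seed) generate
#'   bit-identical data.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n, block_sizes, q, r_true,
                           x_loadings, y_loadings,
                           noise_sd_x = 0.1, noise_sd_y = 0.1,
                           response_center = 45, response_scale = 8,
                           column_names = NULL, response_names = NULL,
                           seed = 1L) {
  if (is.null(names(block_sizes)))
    names(block_sizes) <- paste0("block", seq_along(block_sizes))
  if (r_true < 1 || r_true != round(r_true))
    stop_spec("'r_true' must be a positive integer")
  if (noise_sd_x < 0 || noise_sd_y < 0)
    stop_spec("noise standard deviations must be >= 0")
  if (!is.list(x_loadings) || !setequal(names(x_loadings), names(block_sizes)))
    stop_spec("'x_loadings' must be a named list matching 'block_sizes'")
  x_loadings <- x_loadings[names(block_sizes)]
  for (bn in names(block_sizes)) {
    a <- as.matrix(x_loadings[[bn]])
    if (nrow(a) > block_sizes[[bn]])
      stop_spec(sprintf("block '%s': loading rows (support indices) exceed p_t = %d",
                        bn, block_sizes[[bn]]))
    if (nrow(a) != block_sizes[[bn]] || ncol(a) != r_true)
      stop_spec(sprintf("block '%s': loadings must be %d x %d",
                        bn, block_sizes[[bn]], r_true))
    x_loadings[[bn]] <- a
  }
  y_loadings <- as.matrix(y_loadings)
  if (nrow(y_loadings) != q || ncol(y_loadings) != r_true)
    stop_spec(sprintf("'y_loadings' must be %d x %d", q, r_true))
  if (is.null(column_names))
    column_names <- lapply(stats::setNames(names(block_sizes), names(block_sizes)),
                           function(bn) paste0(bn, "_", seq_len(block_sizes[[bn]])))
  if (is.null(response_names)) response_names <- paste0("y", seq_len(q))
  structure(
    list(n = as.integer(n), block_sizes = block_sizes, q = as.integer(q),
         r_true = as.integer(r_true),
         x_loadings = x_loadings, y_loadings = y_loadings,
         noise_sd_x = noise_sd_x, noise_sd_y = noise_sd_y,
         response_center = response_center, response_scale = response_scale,
         column_names = column_names, response_names = response_names,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a multi-block dataset with planted signal
#'
#' Draws factor scores `F` (`n x r_true`, standard normal), sets
#' `X_t = F A_t' + noise` and `Y = center + scale * (F D' + noise)`, where
#' `A_t` and `D` are the loading matrices of the spec. Inactive covariates
#' (all-zero loading rows) are pure noise. The returned ground truth records
#' the planted structure for recovery tests.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `data` (a [block_dataset()]) and `truth` (class
#'   `ground_truth`: factor `scores`; `active` data frame of (block, column)
#'   pairs; `signal_responses`; per-block `sign` matrices `sign(A_t D')`
#'   giving the planted coefficient signs).
#' @export
generate_multiblock <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n; r <- spec$r_true
  Fscores <- matrix(stats::rnorm(n * r), n, r)
  blocks <- lapply(names(spec$block_sizes), function(bn) {
    A <- spec$x_loadings[[bn]]
    x <- Fscores %*% t(A) +
      spec$noise_sd_x * matrix(stats::rnorm(n * nrow(A)), n, nrow(A))
    colnames(x) <- spec$column_names[[bn]]
    x
  })
  names(blocks) <- names(spec$block_sizes)
  y_lat <- Fscores %*% t(spec$y_loadings) +
    spec$noise_sd_y * matrix(stats::rnorm(n * spec$q), n, spec$q)
  y <- spec$response_center + spec$response_scale * y_lat
  colnames(y) <- spec$response_names

  active <- do.call(rbind, lapply(names(spec$block_sizes), function(bn) {
    idx <- which(rowSums(spec$x_loadings[[bn]] != 0) > 0)
    if (!length(idx)) return(NULL)
    data.frame(block = bn, column = spec$column_names[[bn]][idx],
               stringsAsFactors = FALSE)
  }))
  if (is.null(active)) active <- data.frame(block = character(0), column = character(0))
  signs <- lapply(spec$x_loadings, function(A) {
    s <- sign(A %*% t(spec$y_loadings))
    dimnames(s) <- list(NULL, spec$response_names)
    s
  })
  for (bn in names(signs)) rownames(signs[[bn]]) <- spec$column_names[[bn]]

  truth <- structure(
    list(scores = Fscores, active = active,
         signal_responses = spec$response_names[rowSums(spec$y_loadings != 0) > 0],
         sign = signs, spec = spec),
    class = "ground_truth"
  )
  list(data = block_dataset(blocks, y), truth = truth)
}

#' Study-shaped preset: 5 muscles x 20 biomarkers + performance block
#'
#' Returns a [synthetic_spec()] emulating the tenderness-biomarker design:
#' `n = 10` carcasses; five 20-biomarker blocks named GB, SM, ST, TB, VL
#' (gluteobiceps, semimembranosus, semitendinosus, triceps brachii, vastus
#' lateralis) sharing one protein panel (calpains, heat-shock proteins,
#' metabolic and structural proteins); a sixth 2-column block `perf`
#' (age, weight) carrying no signal; `q = 5` tenderness responses named
#' after the muscles on a 0--100 scale.
#'
#' The planted signal uses two latent factors. Factor 1 is a shared
#' tenderness axis loading on mu-calpain and m-calpain of GB and m-calpain of
#' TB and driving the SM and VL responses with the same sign (population
#' correlation about 0.86). Factor 2 is a muscle-contrast axis loading on
#' h2afx and Hsp40 of GB and on mu-calpain and Hsp70-8 of TB, driving VL
#' positively and SM negatively (population correlations about +0.77 / -0.20),
#' so the second biomarker group flips sign between the two predicted
#' responses. GB, ST and TB responses carry no signal, as do the SM, ST and
#' VL blocks and the performance block.
#'
#' @param noise_sd additive Gaussian noise sd for covariates and (latent
#'   scale) responses; the default 0.1 is "low noise" relative to the
#'   unit-variance planted signal.
#' @param seed integer seed.
#' @param abundance_scale if `TRUE`, biomarker columns are affinely mapped to
#'   typical dot-blot relative-abundance levels (block-specific means around
#'   60--300 units, spread 15) for cosmetic realism; off by default since
#'   standardization removes it.
#' @return a [synthetic_spec()].
#' @export
study_preset <- function(noise_sd = 0.1, seed = 1L, abundance_scale = FALSE) {
  proteins <- c("Hsp20", "Hsp27", "Hsp40", "Hsp70-8", "Hsp70-1b", "GRP75",
                "alphaB-crystallin", "Dj1", "PRDX6", "SOD1", "MyBP-H",
                "Mylc-1f", "MyHCIIx", "ENO3", "h2afx", "PGM1", "TP53",
                "alpha-actin", "m-calpain", "mu-calpain")
  muscles <- c("GB", "SM", "ST", "TB", "VL")
  block_sizes <- c(stats::setNames(rep(20L, 5), muscles), perf = 2L)
  column_names <- c(lapply(stats::setNames(muscles, muscles), function(m) proteins),
                    list(perf = c("age", "weight")))

  # Two factors; loadings fixed so the planted coefficient-sign pattern is
  # (+,+) for the calpain group and (-SM, +VL) for the h2afx/Hsp40/Hsp70-8
  # group. Secondary weight delta keeps the contrast group visibly correlated
  # with VL while weakly anti-correlated with SM.
  delta <- 0.35
  g2 <- c(delta, 1) / sqrt(1 + delta^2)
  zero <- function(p) matrix(0, p, 2)
  A <- lapply(block_sizes, zero)
  A$GB[match(c("mu-calpain", "m-calpain"), proteins), 1] <- 1
  A$GB[match("h2afx", proteins), ] <- g2
  A$GB[match("Hsp40", proteins), ] <- g2
  A$TB[match("m-calpain", proteins), 1] <- 1
  A$TB[match("mu-calpain", proteins), ] <- g2
  A$TB[match("Hsp70-8", proteins), ] <- g2

  gamma <- 0.6
  D <- matrix(0, 5, 2)
  rownames(D) <- muscles
  D["SM", ] <- c(1, -gamma) / sqrt(1 + gamma^2)
  D["VL", ] <- c(1, gamma) / sqrt(1 + gamma^2)

  synthetic_spec(
    n = 10, block_sizes = block_sizes, q = 5, r_true = 2,
    x_loadings = A, y_loadings = D,
    noise_sd_x = noise_sd, noise_sd_y = noise_sd,
    response_center = 45, response_scale = 8,
    column_names = column_names, response_names = muscles,
    seed = seed
  ) -> spec
  if (abundance_scale) spec$abundance_scale <- TRUE
  spec
}

# Typical relative-abundance levels used by the cosmetic abundance_scale
# option of study_preset (arbitrary dot-blot units; spread fixed at 15).
.abundance_levels <- function() {
  m <- c(152, 118, 112, 123, 155, 147, 211, 110, 110,  68, 140,  74,  28, 121, 127, 132,  94,  92, 120, 136,
         150, 129, 162, 141, 188, 153, 195, 125, 110,  95, 128, 109,  33, 134, 173, 165, 142,  89, 139, 175,
          95, 101, 118, 105,  85, 119, 147,  95,  97,  79, 102,  78,  27, 103, 137, 121, 106,  82, 106, 123,
          99, 111, 117, 129, 146, 155, 153, 114, 110,  62, 144,  89,  29, 133, 139, 132, 104,  96, 126, 118,
          68,  86,  99, 156,  81, 122, 156, 101, 115,  58, 101,  47,  45,  83, 226, 306, 153,  99, 214, 134)
  matrix(m, nrow = 5, byrow = TRUE,
         dimnames = list(c("GB", "SM", "ST", "TB", "VL"), NULL))
}

#' @rdname generate_multiblock
#' @details For presets created with `study_preset(abundance_scale = TRUE)`
#'   the muscle-block columns are mapped to `15 * x + typical_level` after
#'   generation.
#' @export
generate_study_data <- function(spec) {
  out <- generate_multiblock(spec)
  if (isTRUE(spec$abundance_scale)) {
    lv <- .abundance_levels()
    for (bn in intersect(rownames(lv), names(out$data$blocks))) {
      b <- out$data$blocks[[bn]]
      out$data$blocks[[bn]] <- sweep(15 * b, 2, lv[bn, seq_len(ncol(b))], "+")
    }
  }
  out
}

#' Serialize a synthetic spec to YAML
#' @param spec a [synthetic_spec()].
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
write_spec_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  payload <- spec
  payload$x_loadings <- lapply(spec$x_loadings, function(a)
    lapply(seq_len(nrow(a)), function(i) as.numeric(a[i, ])))
  payload$y_loadings <- lapply(seq_len(nrow(spec$y_loadings)), function(i)
    as.numeric(spec$y_loadings[i, ]))
  payload$block_sizes <- as.list(spec$block_sizes)
  yaml::write_yaml(unclass(payload), path, precision = 17)
  invisible(path)
}

#' Load a synthetic spec from YAML
#' @param path YAML path written by [write_spec_yaml()].
#' @return a [synthetic_spec()].
#' @export
read_spec_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  as_loading <- function(rows, r) {
    do.call(rbind, lapply(rows, function(v) matrix(as.numeric(v), 1, r)))
  }
  spec <- synthetic_spec(
    n = y$n, block_sizes = unlist(y$block_sizes), q = y$q, r_true = y$r_true,
    x_loadings = lapply(y$x_loadings, as_loading, r = y$r_true),
    y_loadings = as_loading(y$y_loadings, y$r_true),
    noise_sd_x = y$noise_sd_x, noise_sd_y = y$noise_sd_y,
    response_center = y$response_center, response_scale = y$response_scale,
    column_names = lapply(y$column_names, as.character),
    response_names = as.character(y$response_names),
    seed = y$seed
  )
  if (isTRUE(y$abundance_scale)) spec$abundance_scale <- TRUE
  spec
}
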