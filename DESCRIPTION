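Package: blockpls
Title: Multi-Block Data-Driven Sparse Partial Least Squares for Biomarker Panel Selection
Version: 0.1.0
Authors@R: person("blockpls", "developers", email = "blockpls@example.org", role = c("aut", "cre"))
Description: Supervised selection of biomarker panels from multi-block abundance
    data (several covariate matrices observed on the same individuals) with a
    data-driven sparse partial least squares model: per-block soft-thresholding
    of the response cross-covariance, rank-R singular value decompositions,
    super-weight aggregation across blocks and pseudo-inverse regression.
    Includes leave-one-out MSEP model selection over the (R, L0) grid,
    univariate screening statistics (Pearson correlation screens with a
    magnitude retention rule, one-way ANOVA across groups), a synthetic
    multi-block data generator with planted sparse low-rank signal for
    validation, reporting utilities and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
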