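---
title: "Multi-block sparse PLS biomarker selection: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-block sparse PLS biomarker selection: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockpls)
```

## The model and its assumptions

`blockpls` implements a data-driven sparse partial least squares (ddsPLS)
regression for multi-block designs: $T$ covariate matrices
$X_t \in \mathbb{R}^{n \times p_t}$ observed on the same $n$ individuals and
a response matrix $Y \in \mathbb{R}^{n \times q}$, with selection of a small
covariate panel as the primary output. The assumptions are those of any
covariance-based PLS:

* relations are **linear** on the standardized scale,
  $Y \approx \sum_t X_t B_t$;
* signal is **low-rank**: at most $R \le q$ latent directions, because the
  per-block weights come from an $R$-dimensional SVD of a $q \times p_t$
  matrix whose rank cannot exceed $q$;
* relevance is measured by **marginal cross-covariance**: a covariate whose
  correlation with every response is small is (correctly or not) invisible
  to the thresholding step.

There is no deflation. All $R$ components of a block are taken at once from
one SVD of the soft-thresholded cross-covariance
$S_\lambda\!\left(Y^\top X_t/(n-1)\right)$, with
$S_\lambda(x) = \mathrm{sign}(x)(|x|-\lambda)_+$.

Both $Y$ and every $X_t$ are standardized (mean 0, sd 1 with denominator
$n-1$, matching the $n-1$ of the covariance). Standardizing $Y$ gives the
MSEP its reference level of 1; standardizing $X$ is our choice where the
method's description is silent: the thresholding is scale-sensitive and
abundance units are heterogeneous across biomarkers, so on the raw scale
$\lambda$ would not be comparable across columns.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `R` | components per block (and super-components) | grid `1..q` | bounded by `q`, the rank of the cross-covariance |
| `L0` | max covariate columns surviving across all blocks | grid `1..30` | the conventional ceiling of 30 out of ~100 candidates; unitless count |
| `lambda` | soft threshold | derived from `L0` | see below; never set directly |
| `threshold` (screen) | retention cut on \|r\| | 0.55 | the conventional screening magnitude for this design; inclusive at equality |
| `noise_sd` (generator) | additive Gaussian noise sd, both sides | 0.1 | "low noise" relative to unit-variance planted factors |

### The $\lambda \leftrightarrow L_0$ rule

A column of $S_\lambda(Y^\top X_t/(n-1))$ is non-null iff its maximum
absolute entry **strictly exceeds** $\lambda$ (at equality
$(|x|-\lambda)_+ = 0$). Since the survival count only changes at the
distinct per-column maxima, we enumerate exactly those candidates (plus 0)
and take the **smallest $\lambda$ whose count is $\le L_0$**. When exactly
$L_0$ is attainable it is attained; when ties in column maxima make it
unattainable, the largest attainable count below $L_0$ results (possibly
zero — then the fit degenerates to intercept-only, a valid model). This rule
is deterministic under ties, which matters because the printed description
of the secondary condition in the source method is not self-consistent.

### Super-weights

The aggregation step is stated in the source method only as an $R \times R$
object per block "gathering" block information. We implement it as the same
operator one level up: the top-$R$ right singular vectors of
$Y^\top Z/(n-1)$, where $Z$ is the $n \times TR$ concatenation of block
scores $X_t U_t$, sliced into $T$ consecutive $R \times R$ blocks
$\beta_t$, with **no additional thresholding**. This is an assumption, not a
derivation; it is isolated behind `super_weights()` so an alternative can be
swapped in without touching anything else. The final regression of
standardized $Y$ on the $R$ super-components uses an SVD pseudo-inverse.

## Model selection

`loo_msep()` refits *everything* — standardization, $\lambda$, SVDs,
regression — inside each leave-one-out fold; fixing the selected variables
before cross-validating would leak the held-out row into selection and bias
MSEP down. Errors are measured on the response scale standardized with
full-sample parameters, so MSEP = 1 is the mean-prediction reference; an
intercept-only model scores exactly $n/(n-1)$ (each fold's mean moves away
from the held-out point by $y_i/(n-1)$), which the tests verify to 1e-12.

`select_best()` minimizes the response-averaged MSEP; ties within 1e-12 go
to the smaller `L0`, then the smaller `R` (parsimony). Note what this does
*not* do: on a noisy MSEP surface with a broad flat region, the argmin
within the region is essentially random, and parsimony only bites on exact
ties. Nested budgets do produce nested selections (the survival sets are
ranked by column maxima), so walking `L0` up the flat region adds covariates
one at a time rather than reshuffling the panel.

## What the synthetic generator emulates — and what a green test establishes

`generate_multiblock()` draws $r_{\text{true}}$ i.i.d. standard-normal
factor scores per individual, builds active covariates as fixed-sign
loadings on those factors plus $\mathcal{N}(0, \sigma_x^2)$ noise, inactive
covariates as pure noise, and responses as factor loadings plus noise mapped
affinely to a 0–100-like scale (default $45 \pm 8$: panel scores for this
kind of trait cluster in the 30–60 range with an among-individual spread of
roughly 6–8 points). The `study_preset()` mirrors the motivating design:
$n = 10$, five 20-biomarker muscle blocks (GB, SM, ST, TB, VL), a 2-column
performance block with no signal, five responses named after the muscles.
Factor 1 is a shared axis (mu- and m-calpain in GB, m-calpain in TB,
driving SM and VL together, population $|r| \approx 0.86$); factor 2 is a
muscle contrast (h2afx and Hsp40 in GB, mu-calpain and Hsp70-8 in TB,
population $|r| \approx 0.77$ with VL and $\approx -0.20$ with SM), so the
second group's coefficient signs flip between the two predicted responses.

The generator does **not** emulate: dot-blot measurement error structure,
inter-assay batch effects, rater effects in sensory panels, between-block
correlation of the noise, non-Gaussian abundance distributions, or
log-scale effects (an optional pre-transform exists but defaults to none,
since the source protocol does not state one).

Hence what a green test establishes: that the pipeline recovers planted
linear low-rank sparse structure under i.i.d. Gaussian noise at the stated
sizes — exactly (to 1e-8) when noiseless, reliably at $n = 50$ with noise
0.1. It does not establish field performance on real abundance data.

### The hard limit at $n = 10$

One acceptance-grade simulation deliberately runs the full pipeline at the
study's own size ($n = 10$, 102 covariates) and asks for clean qualitative
replication (performance block never selected; signal-free responses
constant; listed coefficients only from the planted blocks with planted
signs) in at least 80% of seeds. The suite leaves this red, and the reason
is instructive: at $n = 10$ a null sample correlation has sd $1/3$, so the
maximum over the ~475 null covariate–response pairs lands around 0.75–0.9
in most runs, while the planted population correlations are capped near
0.86/0.77 by the sign-flip geometry itself (a covariate aligned with
SM + VL and one aligned with VL − SM cannot both be near 1 when SM and VL
share a factor). Sampled signal therefore interleaves with the null
extremes, and any budget wide enough to capture the panel also admits
chance passengers. No noise setting fixes this — null correlations are
scale-free — and the measured rates are computed (and printed) by the
acceptance test itself. A single clean selection table at $n = 10$, like
the one that motivated this package, should be read as one fortunate
realization; the method's own authors warn against generalizing from it,
and this simulation quantifies why.

## Numerical choices

* **SVD sign convention**: the largest-magnitude entry of every
  singular-vector column is made positive, so weights and reported signs are
  platform-reproducible.
* **Rank cuts**: singular values below $10^{-12} \times$ the largest are
  treated as zero in the weight SVDs; the pseudo-inverse cuts at
  $10^{-10} \times$ the largest.
* **Exactly-zero sparsity**: rows of $U_t$ (and hence $B_t$) for
  thresholded-out covariates are set to exact zeros, not left at ~1e-17, so
  "selected" is decidable by `!= 0`.
* **Constant columns** are centered, flagged, and given scale 1 rather than
  rejected (degenerate synthetic cases stay usable); their correlations are
  `NA` and never retained by the screen.
* **Canonical row order**: `loo_msep()` sorts rows by `row_ids` before
  folding, making MSEP *exactly* (bitwise) invariant to row permutations
  instead of merely up to summation order. This requires unique row ids,
  which the container enforces anyway.
* **Serialization**: model JSON is written with 17 significant digits;
  reloaded models predict bit-identically.
* **NIPALS** (kept as an independent oracle for the first weight at
  $\lambda = 0$): convergence when successive `u` change by less than 1e-12,
  cap 500 iterations.

## Other design decisions taken here

* The magnitude screen ($|r| \ge 0.55$, inclusive) and classical p-values
  answer different questions; both are computed, neither is merged into the
  other, and retention is decided by magnitude alone.
* Responses with all-zero thresholded rows are explicitly "unselected":
  their regression columns are zeroed and they are predicted by their
  training mean, rather than receiving incidental nonzero coefficients
  through the shared super-components.
* Training $R^2$ ($1 - \mathrm{SSE}/\mathrm{SST}$, original units) and
  cross-validated $R^2$ ($1 - \mathrm{MSEP} \cdot n/(n-1)$, from LOO errors)
  are both reported, labelled, because a selection table's $R^2$ is
  ambiguous without that label.
* Multiple-comparison letter displays for the per-biomarker ANOVA are out of
  scope (no procedure to reproduce was specified); group means and the
  classical F/p are reported.
* Missing values are a hard error everywhere: this version does not impute,
  and the missing-row capability of the wider method family is explicitly
  out of scope.

## Known limitations

* Single cross-validation layer: the reported MSEP of the *selected* model
  is itself an optimistic estimate (no nested CV); treat it as a model
  selection criterion, not a generalization error.
* k-fold / repeated CV variants are not implemented (LOO only, matching the
  design size this package targets).
* The super-weight construction is an interpretation of an under-specified
  step (above); comparisons with other implementations of the method family
  should expect agreement in selection but not necessarily in coefficients
  beyond the first component.
* The classification variant of the method (LDA on super-components) is not
  implemented.
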