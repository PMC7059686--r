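---
title: "Quantifying workflow-step variability in LC-MS proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying workflow-step variability in LC-MS proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(wfvar)
library(dplyr)
```

## The problem

An LC-MS proteomics experiment is a chain of choices: how tissue is stored,
how protein is extracted, which chromatography and instrument settings are
used, how often a sample is re-run. Each choice contributes technical
variability to the quantified peptide/protein intensities, and a laboratory
standardizing its workflow wants, for every step, the option that
contributes the *least*. wfvar supports that decision with two complementary
per-feature statistics computed on the same preprocessed matrix:

* a fixed-effects ANOVA/ANCOVA **sum-of-squares (SS) decomposition** — for
  every feature, how much of its total variation is attributable to each
  design variable (storage method, extraction method, MS run, subject age,
  ...), reported as a percentage of the feature's total SS; and
* per-group **coefficients of variation (CV)** — for every level of every
  categorical variable, `100 * SD / mean` of the feature over the samples at
  that level, so the least-variable *option within* a step can be ranked.

A variable whose SS share dominates is a step worth standardizing first; the
level with the smallest typical CV is the option to standardize *on*.

## The model

For feature $i$ with complete response vector $y_i$ over $n$ samples, wfvar
fits the main-effects linear model

$$y_{ij} = \mu + \beta\, x_j + \tau^{(1)}_{g_1(j)} + \tau^{(2)}_{g_2(j)} +
\dots + \varepsilon_{ij}, \qquad \varepsilon_{ij} \sim N(0, \sigma_i^2),$$

with continuous covariates $x$ entered first and categorical factors
following in the user's order, and decomposes the total SS sequentially
(Type I): each term is credited with the reduction in residual SS it brings
*given the terms before it*. Each term's $F$ statistic is its mean square
over the residual mean square; p-values come from the upper tail of the $F$
distribution, and are adjusted for multiple testing **across features,
separately within each term** (BH by default; Bonferroni, Holm, Hochberg,
Hommel and BY are available). Three consequences of these choices matter in
practice:

* *Covariates first* is the ANCOVA convention: factor effects are assessed
  after adjusting for the covariate. On a balanced, complete design the
  categorical design columns are mutually orthogonal, so the factor SS are
  order-invariant (this is asserted by a test); on unbalanced data the
  sequential decomposition — and hence the ordering of shares — depends on
  the stated term order.
* *Main effects only.* The tool reports one SS per variable; interactions
  are out of scope by design. If a large residual share co-varies with a
  factor combination, that is a sign an interaction exists and a dedicated
  model is warranted.
* *The residual is a share.* `%SS` is computed against the total SS about
  the mean, with the residual reported as its own share, so all shares sum
  to 100 and the residual row shows how much variation no design variable
  explains.

Constant features (zero total SS) get zero shares and missing p-values —
they are kept in the tables but excluded from significance counts, so
degenerate 0/0 statistics cannot poison summaries.

## The pipeline

`run_pipeline()` executes the stages in a fixed order:

* **exclude mode** — drop every feature with any missing value, then
  normalize, then aggregate peptides to proteins if requested;
* **impute mode** — normalize first, impute at the level the data was
  provided (peptides are imputed *before* aggregation), then aggregate.

Imputing after normalization and before aggregation keeps the imputation
model on the scale where intensities are roughly additive-Gaussian and lets
every peptide contribute its observed values. In exclude mode, dropping
first means the quantile-normalization reference distribution is built only
from complete features. Aggregation after normalization in both modes keeps
the two paths on the same scale. The per-stage feature/sample/missing
counts are recorded in the result's `log`, and every user input is echoed to
`inputs.csv` so a run can be reproduced from its output directory alone.

### Normalization options

* `log2` — plain log transform. Non-positive intensities cannot be
  log-transformed; they become missing with a warning stating the count.
  A silent pseudo-count is deliberately avoided: it would shift every
  downstream SS invisibly.
* `QN` — classic mean-of-order-statistics quantile normalization, applied
  to the log2 data (delegated to `limma::normalizeQuantiles`, ties
  averaged). Columns with missing values are mapped through rank
  interpolation against the reference built from observed values, so the
  missingness mask is preserved exactly.
* `VSN` — a variance-stabilizing generalized-log transform fitted on the
  raw data. Per sample, an affine calibration $(a_s, b_s)$, $b_s > 0$, is
  estimated and $h_s(x) = \operatorname{asinh}(a_s + b_s x)/\log 2 + c$
  applied, with $c$ chosen so that at high intensities the transform agrees
  with $\log_2 x$ up to a constant. The calibration minimizes the profile
  negative log-likelihood of a constant-variance additive-error model
  (including the transform Jacobian) by BFGS with an analytic gradient,
  initialized deterministically from column quartiles, converging when the
  relative objective change drops below `1e-8` (at most 200 iterations).
  A pure per-sample scale factor is provably absorbed (tested at factors
  0.5 and 3 to `1e-6`), and top-decile log-ratios match `log2` within 2%.
  The fit needs at least 10 complete features; below that the function
  stops and recommends log2 + QN.
* `none` — pass-through for data normalized elsewhere.

With a `Norm_Imp_Group` metadata column, QN and VSN (and imputation) can run
independently per group; the groups are treated as fully separate
sub-experiments and re-assembled afterwards.

### Imputation options

Both imputers assume MAR/MCAR missingness (left-censored MNAR imputation is
deliberately not offered; the simulator can still *inject* MNAR to study
robustness):

* `KNN` — donors are the k = 10 (default) nearest features by root mean
  squared difference over coordinates observed in both rows; each missing
  cell is the inverse-distance-weighted mean of donor values at that cell,
  with exact-duplicate donors copied verbatim, distance ties broken by
  input order for bit-reproducibility, and rows more than 50% missing
  falling back to column means.
* `SVD` — iterative low-rank completion: initialize missing cells with row
  means, alternate rank-2 (default) truncated SVD reconstruction of the
  missing cells until their relative change drops below `1e-6` or 100
  iterations (non-convergence returns the current fill with a warning and
  a flag). Observed cells are never modified by either method.

The defaults (k = 10, rank = 2, 50% row-missingness fallback) follow the
conventional defaults of the two method families; the original tool names
the methods but no tuning values, so these are declared choices, all
overridable from `analysis_config()` and the CLI.

### CV analysis

CVs are computed on the same preprocessed matrix that enters the model
stage, so the SS and CV rankings refer to the same data. One caveat is
documented rather than hidden: on log-like scales the CV of the transformed
values is *not* the CV of raw intensities — it is a relative-spread measure
on the analysis scale, and comparisons between groups (its purpose here)
remain valid. Cells with non-positive group means or fewer than two
observations are missing rather than infinite.

## The synthetic-data generator

`simulate_dataset()` emulates a two-step workflow experiment laid out as a
three-factor balanced design: storage method M1 (A1/A2), extraction method
M2 (B1/B2/B3), three age-matched biological replicates per cell, each
measured in two MS runs — 36 samples — with 1000 peptides mapping onto 200
proteins. Log2 intensities follow

```
baseline(protein) + offset(peptide) + effect_M1 + effect_M2 + effect_run
  + slope * (age - mean age) + N(0, sigma(M1 level, M2 level)^2)
```

with defaults chosen once, by variance arithmetic, to encode the study
conditions the tool is demonstrated on:

| setting | default | why |
|---|---|---|
| baseline | N(22, 1.5²) log2 units | typical LC-MS dynamic range |
| peptide offset | N(0, 1) | ionization efficiency spread |
| M1 level effects | N(0, 0.5²) per protein | moderate storage effect |
| M2 level effects | N(0, 1²) per protein | twice M1's spread, so M2 dominates the SS |
| run effect | N(0, 0.25²) | small technical run shift |
| age slope | N(0, 0.015²) per year | smallest contribution |
| residual SD | 0.4 × multipliers | A1 = 1.5×A2; B1 = 1.5×, B3 = 1.8× B2 |
| missingness | 5% MCAR | typical after feature filtering |

Two generator choices deserve explanation. First, ages are *age-matched*:
replicate *i* of every design cell sits at the *i*-th evenly spaced age in
25–65, plus N(0, 2²) rounding jitter. Uniformly random ages chance-correlate
with the dominant M2 factor, and with covariates entered first the Age term
would absorb part of M2's SS — age-matching, the standard allocation in a
designed experiment, keeps Age nearly orthogonal to the factors so its share
reflects only its own (smallest) effect. Second, level effects are drawn
*per protein*, so effect directions differ across proteins while the
variance ordering (M2 > M1 > Age; A2 quieter than A1; B2 quietest) is common
— which is exactly what the across-feature medians in the summaries are
designed to detect.

What the generator does **not** emulate: correlated peptide noise within a
protein, intensity-dependent (MNAR) missingness by default, batch drift
within a run, or heavy-tailed contamination. Tests passing on this
generator therefore demonstrate the statistical machinery under its stated
assumptions, not robustness to every pathology of real data.

## A worked run

```{r demo}
sim <- simulate_dataset(seed = 1)
sim
config <- analysis_config(
  feature_type = "protein", analysis_method = "impute_mv",
  imputation = "SVD", normalization = "VSN",
  categorical_vars = c("M1", "M2", "Run"), continuous_vars = "Age",
  seed = 1)
result <- run_pipeline(sim$expression, sim$metadata, config)
result
```

The `%SS` summary puts M2 (extraction) far above M1 (storage) with Age
least, and the CV summary ranks A2 below A1 and B2 below both B1 and B3 —
the data-driven recommendation is "standardize extraction first; choose A2
and B2". The same conclusions hold in at least 18 of 20 independent seeds
(checked by the test suite and `scripts/acceptance.R`).

```{r plots}
autoplot(result, "ss")
autoplot(result, "cv")
```

## Numerical choices and degenerate inputs

* SS conservation (`sum of term SS + residual = total SS`) holds to relative
  `1e-8` and is asserted per feature; the sequential decomposition is
  verified against an explicit nested-projection oracle on 100 random small
  designs.
* Confounded (rank-deficient) designs error with the aliased coefficients
  named; saturated designs (zero residual df) error rather than report
  unusable statistics.
* Distance ties in KNN and order-statistic ties in QN are broken
  deterministically (input order / tie averaging), so identical inputs and
  seeds give byte-identical outputs.
* `log2(0)` becomes missing (with a count in a warning), never an error and
  never silently offset.
* Problem sizes in the test suite follow the demonstration layout
  (1000 peptides × 36 samples, 20-seed replication for the stochastic
  claims; 100-design oracle sweeps; 1000 random vectors for the adjustment
  oracles) — large enough for the claims, small enough to run routinely.

## Known limitations

* Fixed effects only; no mixed models, no empirical-Bayes moderation, no
  interactions. Steps whose variability acts multiplicatively on specific
  factor combinations will surface in the residual share instead.
* The VSN implementation follows the published model contract
  (affine-calibrated glog, variance-stabilization likelihood, log2
  asymptote) and is validated by property, not bug-for-bug against any
  particular implementation of the same model.
* CV on a log-like scale is a relative-spread measure on that scale (see
  above).
* The imputers assume MAR/MCAR; under strong left-censoring both will
  over-impute low intensities.
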