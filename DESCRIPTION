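Package: wfvar
Title: Variability Decomposition for LC-MS Proteomics Workflow Standardization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies, per peptide or protein, the variability contributed by
    each step and choice of a liquid chromatography-mass spectrometry (LC-MS)
    proteomics workflow. Implements a pipeline of peptide-to-protein
    aggregation, log2 / quantile / variance-stabilizing normalization
    (globally or group-wise), KNN and iterative-SVD missing-value imputation,
    per-feature fixed-effects ANOVA/ANCOVA sequential sum-of-squares
    decomposition with multiple-testing adjustment, and per-group
    coefficient-of-variation summaries, so that experimenters can pick the
    least-variable option for each workflow step. Includes a synthetic-data
    generator emulating a three-factor balanced design with a continuous
    covariate, exploratory and result plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
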