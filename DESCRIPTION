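Package: transcompr
Title: Translatable Components Regression for Cross-Species Single-Cell
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a principal-component space (dense or sparse, via
    soft-threshold rank-1 deflation) from one species' single-cell
    expression matrix, projects a second species' cells into that space,
    quantifies per-component cross-species variance explained, selects
    phenotype-predictive components by AIC-optimised logistic regression,
    interprets components by preranked gene-set enrichment with a
    permutation null, and screens drug perturbation signatures against
    component loadings by tie-aware Spearman correlation.  Includes
    single-cell quality-control filtering, highly-variable-gene
    selection, strict one-to-one ortholog mapping, readers and writers
    for Matrix Market, GMT and delimited signature tables, and a
    synthetic paired-species data generator with planted latent factors
    so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    generics,
    withr,
    sandwich,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    fgsea,
    optparse
Config/testthat/edition: 3
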