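Package: phosflow
Title: Quantitative Phosphoproteomics and Binding-Kinetics Analysis for
    Multiplexed Stable-Isotope Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for SILAC-style quantitative phosphoproteomics
    of kinase signalling, with companion kinetic fitting for imaging-based
    binding assays. Provides moderated per-site linear modelling of log2
    ratios with median-variance regularization and Benjamini-Hochberg
    correction, iterative position-specific phosphorylation-motif
    enrichment (motif-X style), kinase-substrate enrichment scoring,
    downshifted-normal missing-value imputation with Pearson/Ward
    hierarchical clustering, proximity-labeling enrichment classification,
    and nonlinear fitting of FRAP recovery traces, FCS autocorrelation
    curves and competition-binding titrations. A synthetic-data module
    generates every input format with known ground truth so the whole
    pipeline is testable without deposited raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
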