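Package: roisem
Title: Effective Connectivity of ROI BOLD Time Series by Exploratory
    Structural Equation Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Region-of-interest pipeline for model-based connectivity
    analysis of block-design fMRI: synthetic cohort generation from linear
    structural networks driven through the canonical haemodynamic response
    function, ROI-level GLM contrasts, psychophysiological interaction
    (PPI) analysis, maximum-likelihood structural equation modelling of
    condition covariances with the classic fit-index panel (chi-square,
    RMSEA, AIC, GFI/AGFI/PGFI, SRMR), exhaustive path-model enumeration and
    ranked exploratory search, cross-condition pathwise comparison with
    Bonferroni control, and stepwise regression of path coefficients onto
    behavioural scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
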