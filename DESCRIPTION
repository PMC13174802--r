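Package: stratgsem
Title: Stratified-GWAS Genetic Correlation Comparison via LD-Score
    Regression and Genomic Structural Equation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates genetic covariance and sampling covariance matrices
    from GWAS summary statistics by multivariable LD-score regression with a
    delete-one block jackknife, converts case-control estimates to the
    liability scale, and tests for divergent genetic correlations between
    subgroup GWAS (for example sex- or age-at-diagnosis-stratified case
    definitions) and external traits.  Comparisons are carried out with
    equality-constrained structural models fitted by diagonally weighted
    least squares with sandwich standard errors, genetic multiple
    regression, and latent-factor residualization, with Benjamini-Hochberg
    control across a trait battery.  A synthetic summary-statistics
    generator with known genetic architecture, ascertainment and sample
    overlap makes every stage testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
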