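Package: scca
Title: Sparse Canonical Correlation Analysis with Permutation-Based
    Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates multivariate similarity between two
    high-dimensional datasets measured on the same samples using sparse
    canonical correlation analysis (SCCA) via a penalized matrix
    decomposition with L1 and nonnegativity constraints. The sparsity
    parameter of each view is selected independently by a
    permutation-based Fisher z-statistic grid search, canonical
    correlations receive permutation p-values, and multiple
    canonical-vector pairs are extracted by matrix-free deflation so the
    cross-product matrix is never formed. Includes a synthetic
    paired-view generator with known sparse loadings, masked NIfTI
    volume input/output for neuroimaging applications such as arterial
    spin labeling perfusion studies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
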