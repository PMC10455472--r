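Package: netdim
Title: Network Dimensionality Analysis via Exploratory Graph Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates the dimensionality of multivariate assessments with
    exploratory graph analysis: a Gaussian graphical model is fit by graphical
    lasso regularization over a penalty path with extended-BIC model selection,
    and dimensions are identified as Walktrap communities of the resulting
    partial-correlation network. A parametric bootstrap quantifies the
    stability of the solution (dimension-count distribution, structural
    consistency of each dimension, item stability), and a refinement pipeline
    removes unstable items and re-estimates the structure. A correlated
    common-factor simulator generates realistic cognitive-battery data for
    validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    MASS,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
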