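Package: surftica
Title: Surface-Based Template ICA for Individual Resting-State Networks in Neonates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Hierarchical Bayesian estimation of individual resting-state
    network maps on the cortical surface from short neonatal fMRI scans.
    Implements empirical population priors built from pseudo test-retest
    dual regression, vertex-wise Gaussian posteriors fitted with an EM
    algorithm, DVARS-based contiguous-block motion censoring, geodesic
    Gaussian surface smoothing by graph heat diffusion, t-statistic and
    Bonferroni engagement maps, winner-takes-all parcellations with cohort
    frequency maps, and vertex-area-weighted connectivity strength with
    partial Spearman age-trend tests. Includes a synthetic surface-cohort
    generator that runs the generative model forward for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
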