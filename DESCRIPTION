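Package: gliomaconn
Title: Graph-Theoretical Analysis of Resting-State Functional
    Connectivity in Glioma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and analyses resting-state fMRI functional
    connectivity in cohorts of low-grade glioma, high-grade glioma and
    healthy-control subjects. Provides a synthetic-cohort generator with
    group-specific region-to-region covariance structure, ROI-level
    denoising (detrending, nuisance regression, band-pass filtering),
    Fisher-z connectivity matrices, thresholded binary graphs with seven
    nodal graph-theoretical metrics computed in compiled code, and
    whole-brain, hemispheric and lobar group comparisons with a
    normality-gated test choice and Benjamini-Hochberg false-discovery
    control, plus seed-based connectograms and an age/tumor-size
    confound screen.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
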