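Package: critmf
Title: Wavelet p-Leader Multifractal Criticality Analysis for Neural Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates signatures of critical brain dynamics from resting-state
    neural time series using wavelet p-leader log-cumulants: self-similarity
    (first log-cumulant, c1, a Hurst-type exponent) and multifractality
    (second log-cumulant, c2) are measured per signal from weighted
    log-regression of cumulants of log-leaders across dyadic scales, with
    block-bootstrap confidence intervals and singularity-spectrum
    construction. Group-level tooling covers ROI averaging, pseudo t-tests
    with maximum-statistics permutation correction, Benjamini-Hochberg FDR
    for clinical-score correlations, and node-wise single-feature logistic
    decoding with a permutation-derived chance threshold. A synthetic-cohort
    generator (circulant-embedding fractional Brownian motion and
    multifractal random walks with known ground truth) makes every pipeline
    stage testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
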