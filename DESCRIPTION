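Package: n400mvpa
Title: Individual-Subject EEG Decoding and ERP Analysis of Lexical-Semantic Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting lexical-semantic (N400-type) processing in
    single subjects from epoched EEG. Implements spatio-temporally
    unconstrained multivariate decoding with leave-one-target-out
    cross-validation and a pairing-preserving permutation null, time-resolved
    and time-by-space (searchlight) decoding with threshold-free cluster
    enhancement and max-statistic correction, classic region-of-interest N400
    analyses with an autocorrelation-matched cluster threshold, bootstrap
    standardised measurement error (SME) data-quality metrics, experimental
    design utilities (bias-minimised condition sequences, power analysis), and
    a synthetic-EEG generator with controllable, heterogeneous condition
    effects for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
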