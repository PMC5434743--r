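Package: cortconn
Title: Cross-Subject Dynamic Causal Cortical Connectivity from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for estimating dynamic, directed cortical connectivity
    from multichannel scalp EEG across a cohort of subjects. Channel-space
    cleaning (zero-phase band-pass filtering, average re-referencing,
    kurtosis-based rejection, Infomax independent component analysis with
    equivalent-dipole screening), independent-component clustering for
    region-of-interest definition, cortically constrained low-resolution
    electromagnetic tomography (cLORETA) on an analytic three-shell
    spherical head model with generalized cross-validation and
    evidence-based refinement of the regularization parameter,
    sliding-window multivariate autoregressive modeling via the Vieira-Morf
    lattice algorithm with six-criterion order selection and model
    validation, short-time direct directed transfer function (SdDTF)
    connectivity, and a cross-subject permutation-bootstrap significance
    procedure with Benjamini-Hochberg false discovery rate control. A
    synthetic-cohort generator with known ground-truth directed coupling
    provides an oracle for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
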