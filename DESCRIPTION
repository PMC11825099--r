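Package: switchmod
Title: Stochastic Two-State Promoter Models and Bimodality Analysis of
    Single-Cell Expression Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying bimodal gene expression in bacteria.
    Implements a reduced stochastic model of transcription and translation in
    which a promoter switches between low- and high-activity states with
    two rate-limiting steps of transcription initiation, exact stochastic
    simulation (Gillespie direct method, Rcpp backend), truncated
    chemical-master-equation and closed-form oracles, classification of
    single-cell expression distributions as unimodal or bimodal (Gaussian
    mixture BIC and kernel-density peak detection), the shape statistics
    d, h and o for bimodal distributions, single-parameter perturbation
    sweeps and growth-phase transition scans, a synthetic flow-cytometry
    data generator, four-anchor cross-fluorophore calibration, and
    hysteresis tracking of distribution shape along condition sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
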