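Package: cohemg
Title: Coherence-Based Filtering of Synergy-Contaminated Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for myoelectric pattern recognition in the presence of the
    poststroke flexion synergy.  Provides Morlet wavelet coherence between
    shoulder-abductor and wrist/finger EMG channels with Monte-Carlo
    significance thresholds, subject-specific and muscle-specific Butterworth
    band-stop filters built from the significant coherence bands, Hudgins
    time-domain feature extraction, linear discriminant classification of hand
    open / grasp / relax, and a synthetic multichannel EMG generator with a
    loading-dependent shared alpha-band synergy drive so that the whole
    before/after-filter experiment can be run end to end without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
SystemRequirements: fftw3
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
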