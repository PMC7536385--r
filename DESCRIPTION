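Package: brainStateDyn
Title: Brain-State Dynamics from Network fMRI Time Series via Gaussian Hidden Markov Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decodes recurring whole-brain states from network-averaged BOLD
    fMRI time series with a Gaussian-emission hidden Markov model fitted to
    temporally concatenated multi-subject runs, and quantifies how state
    dynamics differ between resting state and naturalistic movie viewing.
    Provides temporal preprocessing (volume dropping, zero-phase Butterworth
    band-pass filtering, confound regression, z-scoring), segment-aware
    maximum-likelihood EM fitting with AIC-based selection of the number of
    states, Viterbi decoding, per-subject dynamics summaries (fractional
    occupancy, dwell times, transition matrices), sliding-window inter-subject
    consistency, cross-session Jaccard overlap, Szymkiewicz-Simpson coupling
    of states to stimulus annotations with permutation inference,
    state-conditioned physiological deviations, inter-subject
    representational similarity analysis with Mantel permutation tests, a
    network-based permutation statistic on transition graphs, and a synthetic
    cohort generator with ground truth for recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    signal,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
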