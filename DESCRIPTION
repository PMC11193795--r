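Package: segconn
Title: Event Segmentation Behavior and Directed EEG Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for naturalistic event-segmentation studies:
    interval coding of boundary keypresses and mixed-effects logistic
    regression of segmentation probability on situational changes; Morlet
    time-frequency band power with spatiotemporal cluster-based permutation
    testing; DICS beamforming with the Neural Activity Index, DBSCAN source
    clustering and LCMV time-series reconstruction; and nCREANN, a nonlinear
    multivariate autoregressive estimator of directed linear and nonlinear
    connectivity fit by a single-hidden-layer network, with time-shifted
    surrogate significance testing. A synthetic-data module generates every
    input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    signal,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
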