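Package: TemporalPrediction
Title: Hierarchical Temporal Prediction Networks and In-Silico Visual Physiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains stacked single-hidden-layer spatiotemporal convolutional
    networks in which each stack learns to predict the immediate future of its
    input, together with slowness and sparse-autoencoder control objectives and
    weight- or frame-shuffle perturbations. Provides a synthetic natural-movie
    generator (1/f textures under rigid translation), a parametric stimulus bank
    (drifting gratings, plaids, binary noise), an in-silico electrophysiology
    suite (receptive fields by reverse correlation, Gabor fits, circular
    variance, orientation bandwidth, modulation ratio, direction selectivity,
    pattern/component plaid analysis, cell-type classification), and a
    normalized-correlation (CCnorm) readout harness for scoring feature models
    against neural recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    png,
    tiff,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
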