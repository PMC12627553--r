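Package: bowheadPAM
Title: Bowhead Whale Acoustic Presence from Passive Acoustic Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A file-level detection pipeline for bowhead whale (Balaena
    mysticetus) acoustic presence in year-round passive acoustic monitoring
    recordings from ice-covered Arctic waters. Provides a synthetic scene
    generator (frequency-modulated calls and harmonic song units embedded in
    noise with ice-transient and seal-trill confounders, plus gridded sea-ice
    fields with known edge geometry), band-limited log-magnitude spectrogram
    preparation with chunked on-disk storage, a compact convolutional neural
    network detector with its full training protocol (Z-score
    standardization, class weighting, a sensitivity/false-positive-rate model
    save criterion and patience-based early stopping), probability
    thresholding with a seasonally windowed false-positive review workflow,
    hourly and daily acoustic presence aggregation, song occurrence
    tabulation, and sea-ice covariates (mean concentration within a radius
    and signed shortest distance to the ice edge with small-patch exclusion).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    jsonlite,
    geosphere,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'bowheadPAM-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'wav_io.R'
    'scene_synth.R'
    'spectro_prep.R'
    'tile_store.R'
    'detector_net.R'
    'trainer.R'
    'inference_review.R'
    'presence_metrics.R'
    'ice_metrics.R'
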