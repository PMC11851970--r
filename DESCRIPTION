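Package: preictal
Title: Seizure Prediction from Scalp EEG with Spectral Band Profiles and an SVM Voting Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An epoch-level preictal-state classification pipeline for
    multichannel scalp EEG. Recordings are notch- and low-pass filtered, cut
    into labeled 10 s epochs around annotated seizure onsets, and summarised
    per epoch by two feature families: short-time Fourier transform band
    amplitude profiles (delta through gamma) and Pearson channel-correlation
    maps, both normalized against per-subject baseline averages. Normalized
    features are rendered into an image, embedded through a pluggable
    convolutional backbone, and classified by an ensemble of six RBF support
    vector machines whose binary outputs are combined by a rounding vote.
    Includes a synthetic-EEG generator with controllable band power and
    inter-channel correlation, a minimal EDF reader/writer with a plain-text
    seizure-summary parser, stratified 60/20/20 splitting, ablation arms, and
    accuracy/sensitivity/F1/ROC reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
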