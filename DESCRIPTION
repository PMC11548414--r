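Package: ssvepbci
Title: Offline Decoding Pipeline for SSVEP Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for offline analysis of steady-state visual evoked
    potential (SSVEP) brain-computer interface experiments with four
    directional commands mapped to 10/12/15/20 Hz flicker stimuli.
    Implements the flicker-stimulus protocol (sinusoidal grayscale
    sequences, balanced randomized session schedules), a forward-model
    simulator of 16-channel EEG sessions with ground truth (occipital
    SSVEP sources, 1/f background, 50 Hz line interference, frontal eye
    blinks), readers and writers for EDF, XDF and a native delimited
    format, zero-phase filtering and epoching, FastICA decomposition with
    automated ocular-artifact flagging and removal, one-vs-rest common
    spatial pattern (CSP) feature extraction with log-variance features,
    sliding-window segmentation, and LDA/SVM/MLP classification with
    stratified splits, confusion matrices and per-class accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    MASS,
    e1071,
    nnet,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
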