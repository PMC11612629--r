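Package: eegswarm
Title: Multi-Domain EEG Feature Extraction and Swarm-Based Feature
    Selection for Seizure Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic epileptic-seizure detection from
    single-channel EEG. Records are bandpass- and notch-filtered,
    segmented into overlapping windows, and summarised by 35 features:
    five statistics (log-sum, mean absolute value, mean power, standard
    deviation, and adjacent-band ratio) over six discrete-wavelet
    sub-bands, plus Welch log band power in the five clinical frequency
    bands (delta to gamma). A modified binary particle swarm optimiser
    with a Clerc-Kennedy constriction factor searches feature subsets by
    cross-validated classifier accuracy, ranks features by
    fitness-weighted selection frequency, and a Pearson correlation
    filter removes redundant features from the top-ranked set. Support
    vector machine, neural network, random forest, and gradient-boosting
    classifiers are evaluated with stratified k-fold cross-validation,
    sensitivity/specificity/accuracy/F1 metrics, and fold-based
    confidence intervals. A synthetic EEG generator with known class
    structure supports end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    e1071,
    nnet,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
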