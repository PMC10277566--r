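Package: lrpselect
Title: Layer-Wise Relevance Propagation Feature Selection for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains compact convolutional backbones (EEGNet, DeepConvNet,
    ShallowConvNet) on motor-imagery EEG, redistributes each class score back
    onto the extracted feature map with the epsilon-stabilized layer-wise
    relevance propagation (LRP) rule, masks the lowest-importance fraction of
    feature-map positions, and retrains the dense classifier on the masked
    features with a frozen extractor. Ships classical baseline selectors
    (ANOVA F, mRMR, RFE), a synthetic motor-imagery EEG generator with planted
    mu/beta event-related desynchronization, standard preprocessing (band-pass,
    exponential moving standardization, decimation, cue-locked epoching), and
    an evaluation harness (accuracy, confusion matrices, Wilcoxon signed-rank
    comparisons, report tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
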