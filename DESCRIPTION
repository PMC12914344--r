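Package: rtdecide
Title: Model-Based Proton Versus Photon Selection for Prostate Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for normal-tissue-complication-probability
    (NTCP) driven selection between photon (VMAT-like) and proton (IMPT-like)
    radiotherapy for prostate cancer. Generates reproducible synthetic pelvic
    phantoms with clinical target margins and prescription criteria, computes
    modality-contrasted dose maps with analytic depth-dose engines, trains a
    compact encoder-decoder convolutional dose-prediction model on
    three-channel anatomical inputs, derives dose-volume histogram metrics
    with EQD2 fractionation correction, evaluates logistic and
    Lyman-Kutcher-Burman NTCP models, applies a two-step delta-NTCP decision
    rule, and scores decisions with ROC/AUC, sensitivity/specificity and
    paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    RNifti,
    car
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
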