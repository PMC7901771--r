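Package: psiCNN
Title: Multi-Channel Convolutional Networks for RNA Pseudouridine Site
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies RNA pseudouridine sites from uridine-centered
    sequence windows with a multi-channel convolutional neural network.
    Provides structure-aware "merged-seq" one-hot encoding combining each
    base with its dot-bracket secondary-structure symbol, a built-in
    Nussinov maximum-pairing folder plus an RNAfold interface, staged
    5-fold cross-validated hyperparameter tuning, sensitivity,
    specificity, accuracy, Matthews correlation and ROC/AUC evaluation,
    kernel-to-motif sequence logos, and a seeded synthetic-data generator
    with planted motifs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    grid,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
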