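Package: transhfo
Title: Transformer-Based Detection of High-Frequency Oscillations in
    Neuromagnetic Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of high-frequency oscillations (HFOs, 80-500 Hz) in
    one-dimensional magnetoencephalography (MEG) and EEG signals. Implements
    the TransHFO framework: moving-window segmentation and band-pass
    preprocessing, ADASYN-based virtual sample generation adapted to balanced
    gold-standard datasets via an artificial three-bin imbalance, a stacked
    scaled dot-product self-attention classifier trained with RMSprop,
    baseline detectors (logistic regression, a stacked sparse autoencoder,
    and ResDen, the attention-free variant), stratified k-fold
    cross-validation with leakage-safe per-fold augmentation, and a depth by
    augmentation-factor sweep. A seeded synthetic MEG generator produces
    ground-truthed oscillatory-burst segments and continuous recordings so
    the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    glmnet,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
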