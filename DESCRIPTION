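Package: silentspeech
Title: Silent-Speech Phoneme Recognition from Wireless EEG-EMG Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A signal-processing and machine-learning pipeline for mouth-motion
    recognition from mixed EEG-EMG biopotential recordings. Provides a
    synthetic-data generator for temple-EEG/jaw-EMG recordings and silently
    mouthed phoneme datasets, Butterworth band decomposition into the
    conventional EEG bands, moving-window covariance and correlation feature
    traces, pre-versus-movement band-correlation statistics with one-way
    ANOVA, and two classifiers for three-phoneme recognition: a two-layer
    LSTM baseline and a nine-block few-shot 1D convolutional network trained
    with a cosine-similarity contrastive loss, with a training-time data
    augmentation suite and a 10-fold cross-validation harness.
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
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
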