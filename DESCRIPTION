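Package: wavefm
Title: EEG Eye-State Classification with Wavelet Features and a Parallel
    FM+LSTM Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects eye state (open versus closed) from multi-channel EEG.
    Band-limited features are extracted with a continuous Morlet wavelet
    transform, quantile-binned and one-hot encoded into a sparse design
    matrix, and classified by a parallel fusion of a second-order
    factorization machine and a single-layer LSTM trained jointly against
    binary cross-entropy. Includes a band-structured synthetic EEG
    generator, ARFF/CSV readers for the UCI EEG Eye State format, and a
    benchmark harness comparing the hybrid against decision-tree,
    random-forest, logistic-regression and SVM baselines with
    accuracy/precision/recall/F1 reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    foreign,
    jsonlite,
    Matrix,
    e1071,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
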