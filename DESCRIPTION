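Package: strokerisk
Title: Stroke Risk Prediction with Hybrid Clustering, Metaheuristic
    Feature Selection, Fuzzy Risk Coding and an Adaptive-Weight
    Bidirectional LSTM
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a complete tabular stroke-risk modelling pipeline:
    hybrid k-means/genetic-algorithm clustering (HKGA) for missing-data
    handling, independent component analysis with a mean-activation
    component filter, a pooled T-test/Spearman correlation pre-filter
    followed by a wrapper feature selector combining elephant herding
    optimization with a gradient search rule and a local escape operator,
    trapezoidal fuzzy comorbidity risk coding, a bidirectional LSTM
    classifier trained from first principles with an adaptive three-loss
    mutation-selection scheme, confusion-matrix metric reporting, and
    MD5-salted elliptic-curve ElGamal encryption of predicted records.
    Includes a synthetic cohort generator emulating the Kaggle stroke
    prediction CSV dialect so the whole chain is exercisable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
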