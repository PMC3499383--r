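Package: procleave
Title: Prohormone Convertase Cleavage-Site Prediction and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for analysing proteolytic processing of neuropeptide
    prohormones. Reads protein sequences with cleavage annotations,
    enumerates candidate cleavage sites at basic residues, tags sites with
    the dibasic/monobasic motif taxonomy (xxKR, xxRR, RxxR, single-R) and
    computes prevalence statistics. Provides three predictor families --
    a known-motif rule model, L2-regularised logistic regression and a
    one-hidden-layer neural network -- over one-hot amino-acid encodings
    optionally augmented with physicochemical property scales, plus a full
    binary-classification evaluation suite (confusion counts, correct
    classification rate, sensitivity, specificity, predictive powers,
    Matthews correlation, rank-based ROC AUC). A seeded synthetic
    prohormone generator with planted motifs supports end-to-end testing
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
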