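Package: flnet
Title: Fast Learning Network Classifiers with a Repeated-Holdout
    Evaluation Harness
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains fast learning networks (FLN): double-parallel
    feedforward networks whose input weights and hidden biases are drawn
    at random and whose output weights (both the hidden-to-output and the
    direct input-to-output links) are solved in closed form by
    Moore-Penrose least squares. Includes binary diagnostic evaluation
    (accuracy, precision, recall, specificity, F-measure, G-mean,
    Matthews correlation coefficient, single-operating-point AROC and
    threshold-sweep ROC curves), readers for the two Wisconsin
    breast-cancer tabular dialects, stratified repeated 70/30 holdout
    with mean/RMSE/STD aggregation over a hidden-node sweep, and a
    schema-faithful synthetic tumor-feature generator so the whole stack
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
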