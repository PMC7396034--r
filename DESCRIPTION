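Package: cnnbag
Title: Hybrid Convolutional Network and Bagging Classifier for Imbalanced Clinical Tabular Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a small convolutional neural network on tabular clinical
    features encoded as 6x6 single-channel grids, replaces its softmax output
    layer with a bagging ensemble of decision trees over the last
    fully-connected-layer activations, and combines the two with a
    preprocessing pipeline aimed at imbalanced hospital-readmission data:
    missing-value cleaning, minority oversampling (random or SMOTE),
    permutation-importance feature selection, and isolation-forest outlier
    screening. The network forward and backward passes are implemented from
    first principles and verified against finite differences; a synthetic-data
    generator with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    randomForest,
    rpart,
    optparse,
    withr
Config/testthat/edition: 3
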