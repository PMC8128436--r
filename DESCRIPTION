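Package: aptazyme
Title: Structure-Aware Prediction and Forward Design of Hammerhead Ribozyme Switches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing tertiary-interaction ribozyme switches
    (aptazymes) on the sTRSV hammerhead scaffold. Assembles ribozyme
    constructs from loop inserts, predicts secondary structure through a
    pluggable folding backend, encodes the two stem-loops as a binary
    structural tensor, and trains a three-dimensional convolutional
    regressor of basal gene-regulatory activity (log10 GFP/mCherry)
    alongside lasso, SVM and random-forest baselines. Includes sort-seq
    (FACS-Seq) bin-count quantification by interval-censored normal
    fitting, aptamer grafting with exhaustive variable-loop enumeration
    and ranking, structural-segment hold-out evaluation, consensus-motif
    analysis, and a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    e1071,
    randomForest,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse,
    withr
Config/testthat/edition: 3
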