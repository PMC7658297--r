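Package: antioxrf
Title: Antioxidant Protein Classification from Sequence-Derived Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies antioxidant proteins from primary sequence alone.
    Implements the composition of k-spaced amino acid pairs (CKSAAP) and
    conjoint triad (CT) sequence descriptors, SMOTE oversampling and random
    undersampling for class-imbalance correction, max-relevance-max-distance
    (MRMD) feature ranking with incremental classifier-evaluated subset
    selection, random-forest classification, and a complete binary
    evaluation suite (sensitivity, specificity, accuracy, F-score, Matthews
    correlation coefficient, ROC/AUC). Includes a planted-signal synthetic
    sequence generator so the entire pipeline is testable without external
    data, and a YAML-configured pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
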