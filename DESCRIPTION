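Package: mpsdiag
Title: Diagnostic Gene Scoring by Random-Forest Selection and Neural-Network Linearization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end construction of a transcriptomic diagnostic score for
    two-group (case/control) expression studies. Implements probe-to-gene
    collapse by highest median, Welch fold-change/significance screening of
    differentially expressed genes, iterative random-forest feature
    elimination driven by raw out-of-bag permutation importance with
    consensus voting across repeated cycles, training of a single-hidden-node
    back-propagation neural network on gene Z-scores, collapse of the trained
    network to a linear per-gene weight table, computation of the resulting
    molecular prediction score (MPS), and ROC/AUC evaluation. Ships a
    synthetic two-group expression generator with planted differential genes
    so the whole workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nnet,
    pROC
Config/testthat/edition: 3
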