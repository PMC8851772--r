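Package: ddicold
Title: Cold-Start Prediction of Multi-Type Drug-Drug Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-drug interactions (DDIs), including their
    pharmacological type, for drugs that are absent from the known DDI
    network (the cold-start setting). Drug embeddings and per-type relation
    matrices are learned from a multi-relational interaction tensor by
    bilinear (RESCAL-style) factorization with full-batch gradient descent;
    a partial-least-squares regression maps binary drug attribute vectors
    (e.g. binding-protein indicators) onto the learned embedding space so
    that new drugs can be embedded and scored. Includes a seeded synthetic
    data generator with known ground truth, drug-wise cold-start
    cross-validation for new-vs-known (S1) and new-vs-new (S2) pairs, and
    per-type AUC/AUPR/F1 evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
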