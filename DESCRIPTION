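Package: submito
Title: Sub-Mitochondrial Protein Localization Prediction and Annotation Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for fine-grained annotation of mitochondrial proteomes.
    Implements a one-dimensional convolutional neural network that predicts the
    sub-mitochondrial compartment of a protein (outer membrane, inner membrane,
    intermembrane space or matrix) from an Lx30 encoding combining PSI-BLAST
    sequence profiles with the ten Kidera physico-chemical factors; per-class
    Matthews correlation coefficient scoring with stratified cross-validation;
    a two-out-of-three majority-vote screen that combines external subcellular
    localization predictors into a mitochondrial discovery call; and
    similarity-based Gene Ontology annotation transfer via identity/coverage
    sequence clustering and Bonferroni-corrected Fisher enrichment. Synthetic
    proteome, profile and annotation generators make every stage testable
    without external data or services.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
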