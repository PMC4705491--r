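Package: eccloc
Title: Multi-Label Protein Subcellular Localization with GO Frequency
    Features and Ensembles of Classifier Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the subcellular location set of bacterial proteins as a
    multi-label classification problem. Query proteins are represented by
    gene-ontology (GO) term frequency vectors built from their typical
    homologous set (homology-search hits above a pairwise-similarity
    threshold), with a 420-dimensional amino acid plus dipeptide composition
    encoding as a backup for proteins lacking a usable GO representation.
    Prediction uses an ensemble of classifier chains (ECC) over a linear
    support vector machine base learner, with binary relevance and single
    classifier chains also exposed. Includes jackknife (leave-one-out)
    evaluation with overall locative and absolute accuracy and per-location
    success rates, a seeded synthetic-data generator, readers and writers for
    FASTA, tabular homology hits, GO annotation tables (two-column TSV or
    GAF 2.x), MatrixMarket feature matrices, and a JSON model archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
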