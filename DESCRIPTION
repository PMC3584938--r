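Package: gopred
Title: Sequence-Homology GO Function Prediction and CAFA-Style Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Gene Ontology (GO) annotations for protein targets from
    parsed sequence-database search results (BLAST/PSI-BLAST tabular output)
    using five homology-based scoring methods -- PFP co-occurrence scoring with
    parental transfer and empirical p-value calibration, the two-level Extended
    Similarity Group (ESG) scheme, GOtcha I-scores, a maximum-identity BLAST
    baseline, and a database-frequency Prior (plus Prior-enriched variants) --
    and evaluates prediction sets with the CAFA assessment metrics: threshold
    and top-N precision/recall/specificity, information-content-weighted
    precision/recall, Resnik-style semantic similarity, and term-centric F1.
    Includes OBO/GAF/BLAST-tabular readers and a seeded synthetic benchmark
    generator so the full pipeline runs at desk scale without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    methods,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
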