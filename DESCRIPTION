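Package: sitedriver
Title: Prioritizing Cancer Driver Mutations at Allosteric and Orthosteric Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps missense mutations from clinical cancer samples onto
    experimentally verified allosteric sites, predicted allosteric sites and
    orthosteric sites of human proteins, scores each site-mapped mutation with
    a class-rebalanced (SMOTE) random-forest plus multi-layer-perceptron
    ensemble, and ranks candidate driver proteins per sample. Includes parsers
    for MAF, ANNOVAR and plain mutation-list input, a site-database loader,
    a fixed-schema featurizer built on standard residue property tables,
    ROC/AUC benchmarking utilities, seeded synthetic-data generators for all
    inputs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
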