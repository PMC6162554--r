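Package: epiweight
Title: Interaction-Weight Forward Search for High-Order SNP Epistasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects k-way single-nucleotide polymorphism (SNP) interactions
    associated with a binary disease phenotype in case-control genotype data.
    Implements the FDHE-IW strategy: a modified symmetrical-uncertainty screen
    ranks SNPs as search seeds, a forward search driven by multiplicative
    interaction-weight factors assembles candidate k-way combinations, and an
    improved G-test with small-cell gating and adaptive degrees of freedom
    verifies candidates. Includes a penetrance-table case-control simulator in
    the style of GAMETES, k-nearest-neighbour genotype imputation, bootstrap
    class balancing, and power/recall/precision/F-measure evaluation metrics,
    so the full pipeline is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
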