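Package: phylostrat
Title: Phylogenetic Age Estimation and Enrichment Analysis for Protein Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Assigns phylogenetic ages to proteins from the presence and
    absence of their families across a dated species tree, using Dollo or
    asymmetric Wagner (Sankoff) parsimony ancestral reconstruction. Each
    protein is dated by the branch on the path between its species and the
    root on which its family is inferred to have appeared. Includes
    age-enrichment comparisons between protein sets (two-sided Mann-Whitney
    U test plus per-age-stratum Fisher's exact tests), correlation of age
    with quantitative protein features (Spearman rank correlation, box-plot
    summaries, linear trends), phylogenetic profiles, domain-based age
    strategies, a simulator of family gain and loss with known ground
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    ape,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
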