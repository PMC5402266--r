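Package: tsnetwork
Title: Tissue-Specific Coexpression Networks from Multi-Tissue Expression Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies tissue-restricted genes from a multi-tissue expression
    matrix with the tissue-specificity index (TSI), builds a thresholded
    Pearson coexpression network over the selected genes, partitions it with
    a from-scratch Markov Cluster (MCL) implementation, tests gene-set
    overrepresentation (hypergeometric with Benjamini-Hochberg adjustment,
    plus a permutation alternative), and compares derived-allele-frequency
    distributions between gene sets with bootstrap confidence intervals.
    Includes a seeded synthetic-data generator with ground-truth manifests
    and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
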