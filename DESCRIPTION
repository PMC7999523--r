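Package: genofabric
Title: Genomic Fabric Analysis of Transcript Abundance, Variability and
    Coordination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Treats the expression of each gene as three independent
    characteristics: its level, its relative expression variability (a
    chi-squared interval-corrected pooled coefficient of variation across
    biological replicas and redundant microarray spots), and its pairwise
    Pearson coordination with every other gene.  Provides spot-level
    quality filtering and iterative median normalization for two-color
    microarrays, redundancy-group aggregation, gene expression stability
    percentiles, per-gene adaptive fold-change cut-offs for differential
    expression, replicate-wise coordination networks with
    synergistic, antagonistic and independent calls, coordination-profile
    similarity, pathway fabric remodeling summaries, standardized
    hypergeometric gene-set enrichment with permutation p-values, and a
    seeded synthetic two-color microarray generator with planted ground
    truth for end-to-end validation.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
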