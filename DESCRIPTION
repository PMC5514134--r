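Package: motifnet
Title: Cis-Regulatory Motif Target Discovery in Gene Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bottom-up discovery of promoter-motif-regulated gene modules.
    Builds a graphical-Gaussian-model (shrinkage partial correlation)
    co-expression network from an expression matrix, scans repeat-masked
    promoters for motif occurrences with an exact score-distribution p-value
    threshold, identifies motif target genes over seeded network
    neighborhoods via hypergeometric motif enrichment and a TSS
    position-bias Z statistic, estimates the false discovery rate by
    promoter randomization, partitions the target sub-network into modules
    with Markov clustering, and scores modules for annotation and
    TF-binding enrichment. Includes a synthetic-data generator with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
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
    withr,
    yaml
Suggests:
    Biostrings,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
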