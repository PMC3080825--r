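Package: epiddag
Title: Bayesian-Network Scoring of SNP Epistasis with Direct DAG Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects gene-gene (epistatic) interactions in case-control
    genotype data by exhaustively scoring direct directed-acyclic-graph
    (DDAG) Bayesian-network models, in which candidate SNPs are parents of
    a binary disease node.  Implements the Bayesian (K2 and BDeu with
    tunable prior equivalent sample size), minimum-description-length
    (Suzuki, AIC, and an epistasis-tailored bit-length penalty), and
    minimum-message-length scoring criteria; a two-locus pure-epistasis
    penetrance-table simulator with controlled broad-sense heritability
    and minor allele frequency; a two-stage anchored screen for larger
    marker panels; a minimal multifactor dimensionality reduction (MDR)
    baseline; and an evaluation harness (top-model accuracy, recall,
    McNemar comparisons, marker-hit reports).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
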