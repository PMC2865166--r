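Package: molevolkit
Title: Comparative Molecular Evolution of Protein-Coding Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for comparative molecular-evolution analysis of
    protein-coding gene families: empirical-Bayes per-site evolutionary
    rates with reverse conservation analysis (sliding-window profiling and
    peak calling), a random-effects-likelihood (REL) scan for positively
    selected codons with per-site Bayes factors under an MG94-style codon
    model, detection of co-evolving codon pairs by substitution mapping
    and Bayesian-network scoring, a birth-death test of gene-family size
    evolution on a dated species tree, codon-usage correspondence
    analysis, and a seeded codon-level sequence simulator that provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    igraph,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    knitr,
    rmarkdown
Config/testthat/edition: 3
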