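Package: cashmere
Title: Convergent Evolution and Selection Analysis of Cashmere Traits
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A multi-stage pipeline for studying convergent adaptation of
    cashmere (secondary hair follicle) traits across ruminants and goat
    populations. Implements Goldman-Yang codon-model likelihood-ratio tests
    for positively selected and rapidly evolving genes, ancestral protein
    state reconstruction with convergent-substitution detection and a
    conservative-site filter, sliding-window Weir-Cockerham Fst and
    nucleotide-diversity-ratio selective-sweep scans, a weighted
    coexpression network core (soft thresholding, topological overlap,
    module eigengenes, module-trait correlation and hub-gene screening),
    negative-binomial Wald differential expression, and gene-set
    intersection with hypergeometric pathway enrichment. Every stage is
    exercisable on synthetic data with planted ground truth generated by
    the package itself.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    mclust,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
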