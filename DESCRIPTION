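Package: meadowpop
Title: Population Genomics of Clonal Seagrass Meadows
Version: 0.1.0
Authors@R: person("Meadow", "Popgen Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-usable pipeline for range-wide population genomics of
    clonal marine plants such as eelgrass (Zostera marina): a hard-filter SNP
    quality-control cascade with SNP-set derivations, clonemate and selfing
    detection from shared heterozygosity, pangenome presence-absence
    (cloud/shell/core) classification, nucleotide diversity, observed
    heterozygosity, Weir-Cockerham F_ST with bootstrap significance,
    Patterson's D with block-jackknife significance, chloroplast haplotype
    calling and median-joining networks, and molecular-clock dating including
    a net-divergence split-time estimator. A built-in structured-coalescent
    simulator generates every input with ground-truth labels so the whole
    pipeline is exercised by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
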