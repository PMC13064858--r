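Package: coredefensome
Title: Core Defensome Analysis of Bacterial Pangenomes
Version: 0.1.0
Authors@R:
    person("Core Defensome", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Identifies highly conserved anti-MGE defense systems (HCADS) and
    counter-defense systems (HCCDS) from per-genome defense-system annotations.
    Builds reciprocal-best-hit (RBH) protein orthology within species, lifts it
    to system-level conservation blocks, classifies blocks as core (100%
    presence), quasi-core (90-99%) or accessory, detects defense islands
    (clusters of defense systems separated by at most 10 genes, with at least 5
    defense genes from at least 3 families), resolves mobile-genetic-element
    (MGE) overlaps and assigns each system a genomic context, computes
    per-megabase densities, clusters viral contigs into vOTUs by greedy
    centroid ANI clustering, and provides the statistical tests used on the
    outputs. A synthetic pangenome generator with planted ground truth makes
    every stage testable without external data or tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
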