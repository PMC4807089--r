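Package: rnaphage
Title: Discovery and Diversity Analysis of RNA Bacteriophages in
    RNA-Inclusive Metagenomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable, fully testable reimplementation of a discovery
    pipeline for highly divergent RNA bacteriophages in RNA-inclusive
    metagenomic read sets: six-frame translated homology triage with
    Karlin-Altschul E-values, toy greedy overlap assembly, ORF and
    motif-model domain annotation with RdRp palm-motif completeness,
    identity-threshold phylotype dereplication, species delimitation
    across amino-acid identity cutoffs, alignment trimming, distance
    phylogenetics with bootstrap support, and presence/absence
    prevalence and persistence summaries. Includes a synthetic
    levivirus-like community generator with ground-truth tables so
    every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    igraph,
    jsonlite,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Metagenomics, Virome, Sequencing, Alignment, Phylogenetics
RoxygenNote: 7.3.3
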