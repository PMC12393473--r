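Package: autopodreg
Title: Regulatory Element Evolution in the Developing Human Autopod
Version: 0.1.0
Authors@R:
    person("Autopod", "Maintainers", email = "maintainers@autopodreg.org",
           role = c("aut", "cre"))
Description: Tools for linking chromatin accessibility in the developing
    hand and foot (autopod) skeleton to human-specific genomic evolution.
    Provides interval algebra and chain-based liftover on BED-style
    half-open coordinates, classification and anatomical partitioning of
    regulatory-element accessibility atlases, overlap and per-base-pair
    enrichment statistics against evolutionary feature sets (human
    accelerated regions, conserved deletions, quickly evolved regions,
    inversions, structurally divergent regions), a three-species
    outgroup-parsimony procedure that counts lineage-specific fixed
    substitutions inside regulatory elements, conservation-score shift
    testing, and interspecific skeletal proportion change. A synthetic-data
    generator plants known substitutions, polymorphisms, indel-induced
    chain gaps, accessibility sharing structure and score shifts so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
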