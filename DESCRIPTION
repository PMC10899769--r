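Package: teprofiler
Title: Transposable-Element-Centric Epigenomic Profiling
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Aggregates input-subtracted ChIP-seq-style signal over
    hierarchically classified repeat copies (class / family / repeat name),
    tests peak-repeat overlap enrichment against a constrained shuffled
    null, stratifies repeat families by evolutionary clade, builds scaled
    meta-repeat profiles with fixed flanks, decomposes tandem
    retrotransposon clusters, and classifies repeat-level expression
    changes after knock-down.  A seeded synthetic-data generator produces
    toy genomes with planted family enrichments, tandem clusters, peaks
    and negative-binomial count matrices so every pipeline stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
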