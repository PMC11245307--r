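Package: rhinotools
Title: Tile-Based ChIP-Seq Enrichment and piRNA Quantification for
    HP1-Family Heterochromatin Biology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of Rhino-class heterochromatin data in
    Drosophila gonads: generation and curation of fixed-width genomic tiles,
    ChIP-seq enrichment with depth normalization, pseudocounts and
    background-median correction, transposon-consensus enrichment with
    explicit multimapper assignment, small-RNA read trimming and
    categorization with microRNA-based normalization, piRNA counting
    (antisense length-normalized transposon counts, locus-unique cluster
    counts, per-tile fold changes) and a twofold dependence classifier,
    subfamily-discriminative residue scanning of HP1-family alignments, and
    rigid-body chromodomain superposition with steric-clash detection.
    Includes a synthetic-data generator with recorded ground truth so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
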