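Package: smcreg
Title: Cohesin and Condensin II Occupancy at Regulatory Elements and
    Super-Enhancers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for the occupancy of the SMC complexes
    cohesin and condensin II at transcriptional regulatory elements.
    Simulates ChIP-seq read sets and knockdown RNA-seq counts over a toy
    genome with planted enhancers, super-enhancer constituent clusters,
    promoters, gene bodies and heterochromatin domains; quantifies binned
    read coverage in reads-per-million units; calls factor-occupied
    regions against an input control; derives enhancer, promoter and
    heterochromatin classes from factor co-occupancy; aggregates coverage
    into metagene profiles and POL II-ranked gene matrices; stitches
    enhancer constituents and separates super-enhancers from typical
    enhancers with a ranked-signal inflection cutoff; and quantifies the
    expression sensitivity of super-enhancer-associated genes to cohesin
    and condensin II knockdown.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
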