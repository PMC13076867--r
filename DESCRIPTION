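Package: polterm
Title: Nascent-Transcription Termination, Readthrough and
    Transcription-Replication Conflict Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative toolkit for spike-in-normalized nascent RNA-seq
    (POINT-seq/TT-seq style) coverage analysis around transcription
    termination: termination index and downstream-of-gene readthrough,
    pausing index, elongation index profiles, splicing efficiency, scaled
    metagene matrices, classification of replication-initiation zones
    invaded by readthrough polymerase, elongation-rate estimation from
    CDK9-inhibition waves by changepoint calling, and a BrdU-IP
    replication-enrichment pipeline with a Brunner-Munzel rank comparison.
    Includes a seeded synthetic-data generator that plants known
    readthrough, wavefront, splicing and replication structure so every
    metric can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
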