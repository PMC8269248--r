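Package: termscape
Title: Transcript 3'-End Mapping, Terminator Classification, and
    Transcription-Unit Assembly from Term-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls transcript 3'-end positions (TEPs) from replicate
    term-seq 3'-end count tracks by clustering, replicate filtering,
    Z-score screening and a K-nearest-neighbour peak classifier;
    classifies TEPs into intrinsic-terminator-like classes from upstream
    RNA folding free energy and downstream uridine tracts; assembles
    transcription units (TUs) and TU clusters (TUCs) by integrating
    transcription start sites with RNA-seq coverage under a sliding-window
    continuity criterion; and computes downstream statistics
    (read-through fractions, nucleotide enrichment, bidirectional TEPs,
    COG functional enrichment, 3'-UTR lengths, small-protein screening,
    Poisson protein distances). Includes a synthetic-data generator with
    known ground truth so the whole pipeline is testable without any
    external data.
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
    class,
    mclust,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
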