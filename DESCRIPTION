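Package: m6Aforest
Title: Motif-Stratified Random-Forest Detection of m6A from Nanopore
    Fraction-Modified Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls N6-methyladenosine (m6A) sites at single-coordinate,
    isoform-level resolution from per-position fraction-modified signal
    tracks produced by nanopore direct RNA sequencing preprocessing.
    Candidate adenosines inside DRACH motifs are converted to fixed-length
    signal windows, one random-forest classifier is trained per 5-mer motif
    against an incomplete CLIP-derived truth set, qualifying models are
    applied transcriptome-wide, transcript-space calls are lifted to
    genomic coordinates to classify isoform-specific methylation, and
    per-site sensitivity to writer depletion or eraser overexpression is
    scored. A synthetic-fixture generator reproduces the statistical
    structure the classifiers assume for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    pROC,
    randomForest,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
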