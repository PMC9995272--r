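Package: polwave
Title: RNA Polymerase II Pausing and Elongation Kinetics from Nascent
    Transcriptomic Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies RNA polymerase II promoter-proximal pausing and
    transcription kinetics from strand-specific nascent-transcription coverage
    tracks. Computes pausing indices from single-nucleotide 3'-end occupancy
    (mNET-seq-like) data, estimates the half-life of the paused polymerase pool
    from triptolide initiation-block time courses by exponential-decay fitting,
    and estimates productive elongation rates from DRB-release labeled-RNA
    (TT-seq-like) time courses by trimmed-mean metagene construction, spline
    smoothing and advancing wave-peak tracking, plus an elongation-velocity
    proxy (synthesis per polymerase). Includes spike-in normalization, BED12/
    GTF/bedGraph input-output, a negative-binomial simulator with known
    ground-truth kinetics for end-to-end validation, and a reproducible
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    graphics,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    minpack.lm,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
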