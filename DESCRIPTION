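Package: footprintr
Title: Differential Chromatin Accessibility and Bias-Corrected
    Transcription Factor Footprinting for ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a universal ATAC-seq peak atlas from per-sample peak
    calls, scores and variance-stabilizes peak counts, calls differential
    accessibility between sample sources with a negative-binomial Wald
    test and covariates, tests motif enrichment in differential peaks
    against GC-matched background peaks with Fisher's exact test, and
    computes transcription-factor footprint profiles corrected for Tn5
    hexamer sequence bias, summarized as flanking accessibility and
    footprint depth. Includes a synthetic-data module (genomes, planted
    motif instances, hexamer-biased cut sites with footprint protection,
    negative-binomial count matrices) so that every stage is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    MASS,
    methods,
    stats,
    utils
Suggests:
    DESeq2,
    SummarizedExperiment,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
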