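Package: polycage
Title: Polysome-CAGE Analysis of Alternative Promoter Usage and Translation
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing strand-specific CAGE transcription start
    site (CTSS) count tracks from total RNA and polysome fractions. Calls
    promoter tag clusters with the slice-reduce approach, measures
    interquartile promoter widths and sharp/broad shape classes, detects
    balanced bidirectionally transcribed enhancer candidates with a
    Bhattacharyya balance score and links them to promoters, tests
    differential expression and differential TSS usage with a negative
    binomial Wald model, quantifies per-TSS translation efficiency from
    Free/Light/Heavy polysome fractions, classifies ORF-retaining versus
    ORF-truncating alternative TSSs and their truncation impact, analyses
    cap-proximal start nucleotides (including the repressive CNY
    trinucleotide class), and scans promoter windows for transcription
    factor binding motifs with Fisher enrichment tests. Includes a
    synthetic-data generator that produces a toy genome, annotation, CTSS
    tracks and a ground-truth table for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
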