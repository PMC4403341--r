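Package: regland
Title: Decoding Transcriptional Cell States from the Regulatory Landscape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for decoding two melanoma transcriptional cell
    states (proliferative and invasive) from regulatory genomics data. Builds a
    genome-wide candidate regulatory-region catalog from feature tracks
    (merge, insulator/exon blacklist removal and splitting, minimum-length
    filtering, extension to 1 kb), calls state-specific regions and gene
    signatures from negative-binomial count models, discovers master regulators
    by ranking-and-recovery motif/track enrichment (recovery-curve AUC at a
    0.25 percent cutoff, normalized enrichment scores, hypergeometric tests,
    order-statistics rank aggregation), and maps transcription factor to
    enhancer to gene networks via distance- and correlation-based assignment.
    Includes a synthetic-data module that plants ground-truth regulators,
    differential regions and enhancer-gene links so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
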