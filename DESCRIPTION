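Package: prometh
Title: Comparative Promoter CpG-Island Detection, Regulatory-Element
    Search, and Methylation Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of vertebrate gene promoters,
    built around the UCP1 (uncoupling protein 1) upstream region:
    synteny-gated extraction of anchor-relative upstream sequences from
    genomes and annotations, two-tier CpG-island detection under the
    Gardiner-Garden-Frommer criteria (a seeded maximal-segment scan and an
    exhaustive window scan), affine-gap Smith-Waterman homology search for
    conserved regulatory elements such as the distal UCP1 enhancer, and
    presence/absence reporting across species.  Also quantifies DNA
    methylation from methylation-sensitive restriction-digest qPCR and
    from bisulfite base counts, and computes delta-delta-Ct relative
    expression.  Synthetic-data generators with machine-readable truth
    records allow every stage to be validated end to end without external
    genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
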