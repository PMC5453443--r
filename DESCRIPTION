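Package: promotif
Title: Promoter Cis-Motif Enrichment and Stress Signature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for cis-regulatory motif analysis in plant
    promoters. Extracts strand-aware upstream promoter sequences from a genome
    FASTA and GFF3 gene models, scans them with a degenerate (IUPAC) motif
    library on both orientations, and tests per-motif over-representation in
    differentially expressed gene lists with a one-sided Fisher exact test and
    Bonferroni correction. Further stages project curated signature gene sets
    (e.g. reactive-oxygen-species scavenging families) across species through
    orthogroup tables, run generic gene-set over-representation with
    Benjamini-Hochberg control, and tabulate motif co-occurrence. A
    synthetic-data generator produces complete self-consistent fixtures
    (genome, gene models, motif libraries, differential-expression tables,
    orthogroups, gene sets) with a known truth ledger, so that every stage is
    verifiable by construction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
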