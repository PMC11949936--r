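Package: tilescreen
Title: Tiling CRISPR Screen Design, Counting and Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and analysis of pooled, tiled CRISPR/Cas9 screens that map
    regulatory elements in a genomic interval. Enumerates every SpCas9
    protospacer (20-nt spacer, NGG PAM, both strands) in a target region,
    extracts and counts guide spacers from screen sequencing reads, scores
    per-guide enrichment of a sorted expression-negative population against an
    untreated baseline (replicate medians, log2 fold change, one-sided Welch
    t-test, composite volcano score), calls hits at fold-change and p-value
    cut-offs, predicts dual-guide excision sizes from cut coordinates, and
    computes delta-delta-Ct qPCR fold changes. A seeded simulator generates
    tiling libraries, overdispersed count matrices with known enriched guides,
    and raw reads for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
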