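Package: motifpairs
Title: Paired Transcription Factor Motif Enrichment in Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects enrichment of pairs of transcription factor binding
    motifs in the promoters of gene sets. Motifs given as letter-probability
    matrices are scanned over upstream promoter sequences with exact
    p-values from a dynamic-programming score distribution; per-promoter
    motif presence is scored by the binomial probability of the top k
    non-overlapping hits (1 <= k <= 5); a fixed-size index of the
    best-scoring promoters defines motif presence; overlapping hits of a
    motif pair are resolved by the information content of the overlap; and
    gene sets are tested for paired-motif enrichment with a Bonferroni
    corrected hypergeometric test. Includes a synthetic promoter generator
    with planted motif instances for benchmarking and a command line
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
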