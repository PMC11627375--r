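Package: pleiogene
Title: Multi-Cancer Risk Region Mapping and Candidate Pleiotropic Gene Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps shared (pleiotropic) risk regions across hormone-dependent
    cancers from GWAS index variants and calls candidate target genes. Provides
    a chromosome-preserving permutation test for spatial co-clustering of
    variants from multiple traits, construction of multi-cancer risk regions by
    overlap of flank-extended per-cancer intervals, a thresholded variant
    annotation decision tree (coding consequence, splicing, regulatory
    probability, chromatin state), distal variant-to-gene assignment through
    promoter capture Hi-C interactions prioritised by topologically associating
    domains (with a circularised TAD-shuffle enrichment test), candidate
    multi-cancer gene and lncRNA calling with an auditable evidence trail, and
    Fisher / matched-set permutation enrichment of gene categories. A seedable
    synthetic-data generator produces every pipeline input with controllable
    statistical structure so all stages are testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
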