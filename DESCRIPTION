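Package: regulhap
Title: Regulatory Annotation of Disease-Risk Haplotypes via Histone-Mark
    Enrichment and Chromatin-Loop TAD Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps disease-associated index SNPs to linkage-disequilibrium
    (LD) haplotype blocks, tests those blocks for enrichment of histone-mark
    ChIP-seq peaks against a random-region resampling null with a
    normal-approximation p-value, reconstructs the topologically associated
    domain (TAD) around each block from CTCF HiChIP loops by transitive
    traversal of the loop-anchor graph followed by gap-bounded anchor
    merging, and assigns genes to the reconstructed domains with a
    TPM-based expression filter. Includes a seeded synthetic-data generator
    that emulates every input format (BED peak sets, BEDPE loops,
    chrom.sizes, gene annotation, TPM matrices) with planted structure, so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
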