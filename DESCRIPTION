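Package: methrescue
Title: RRBS Differential Methylation and Genotype-Rescue Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for reduced representation bisulfite sequencing (RRBS)
    methylation-rescue studies across wild-type, knockout and
    catalytically-inactive genotypes: per-CpG differential methylation
    calling, Mann-Whitney-U-based DMR segmentation, weak/strong rescue
    classification, genomic element and imprinted control region annotation,
    stage-to-stage de novo methylation analysis, methylation-expression-
    chromatin integration, and a beta-binomial synthetic cohort generator
    with machine-readable planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
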