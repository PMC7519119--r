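Package: cnvmqtl
Title: Copy-Number Variant Methylation QTL Mapping with Permutation Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association mapping of copy-number variant (CNV)
    genotypes against CpG methylation, gene expression, and
    methylation-expression (eQTM) phenotypes using Spearman rank
    correlation with per-phenotype permutation correction and a
    permutation false-discovery-rate estimator. Includes linkage
    disequilibrium and conditional analysis against SNP genotypes,
    CpG-island shore and genic-context annotation, size-matched interval
    permutation tests for regulatory-feature enrichment, distance-matched
    permutation tests for Hi-C contact enrichment, and seeded synthetic
    cohort generators with planted effects for power and calibration
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    data.table,
    limma,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
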