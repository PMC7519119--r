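#!/usr/bin/env Rscript
# Genomic-context annotation of the significant CNV-mQTLs: CpG
# island+shore regions around associated CpGs, overlap with a
# simulated VMR-like catalog, genic/non-genic classification against a
# simulated gene model set, and imprinted-gene tagging.
source("analysis/00_config.R")

cnvs <- read_matrix(file.path(DATA_DIR, "cnv_genotypes.tsv"), "genotype")
meth <- read_matrix(file.path(DATA_DIR, "methylation_beta.tsv"), "methylation")
rec <- read_associations(file.path(OUT_DIR, "mqtl_associations.tsv"))
sig <- call_significant(rec, CUTOFF)
cfg <- study_config()

# island + 2 kb shore regions around the associated CpGs
assoc_cpgs <- meth$intervals[meth$intervals$id %in% sig$phenotype_id, ]
shores <- define_shores(feature_track("assoc_cpgs", assoc_cpgs),
                        flank = 2000, genome = cfg$chrom_lengths)
write_bed(shores, file.path(OUT_DIR, "assoc_cpg_island_shores.bed"))

# VMR-like catalog biased into the shore regions
vmr <- simulate_feature_track(shores$intervals, bias = 4, cfg,
                              n_features = 200, feature_length = 1500,
                              name = "VMR_like")
ovf <- overlap_fraction(vmr$intervals, shores)
cat(sprintf("VMR-like regions overlapping associated island+shores: %d/%d (%.1f%%)\n",
            ovf$count, ovf$total, 100 * ovf$fraction))

# gene models: deterministic grid of genes with alternating biotypes
withr::with_seed(SEED + 501L, {
  n_genes <- 40
  chrom <- rep(names(cfg$chrom_lengths), length.out = n_genes)
  start <- floor(runif(n_genes) * (cfg$chrom_lengths[chrom] - 2e5))
  genes <- data.frame(chrom = chrom, start = start, end = start + 2e5,
                      id = sprintf("gene%02d", seq_len(n_genes)),
                      biotype = rep(c("protein_coding", "protein_coding",
                                      "lncRNA", "pseudogene"),
                                    length.out = n_genes))
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    es <- start[g] + sort(sample.int(19e4, 4)) ; ee <- es + 2000
    data.frame(chrom = chrom[g], start = es, end = ee, gene_id = genes$id[g])
  }))
})
lab <- classify_cnv_contexts(cnvs$intervals[cnvs$intervals$id %in%
                                              sig$variant_id, ],
                             genes, exons)
write.table(lab, file.path(OUT_DIR, "cnv_context.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("CNV-mQTL genic context (%):\n")
print(round(100 * table(lab$class) / nrow(lab), 1))
cat("subgenic labels among genic CNV-mQTLs:\n")
print(table(lab$subgenic, useNA = "no"))

# imprinted tagging: CpG ids joined to the nearest simulated gene; the
# synthetic catalog is planted to contain two of the associated genes
# (plus one absent id) so the tagging step has known truth
sig_genes <- toupper(unique(genes$id[GenomicRanges::nearest(
  GenomicRanges::GRanges(assoc_cpgs$chrom,
                         IRanges::IRanges(assoc_cpgs$start + 1, assoc_cpgs$end)),
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start + 1, genes$end)))]))
imprinted <- data.frame(gene_id = c(sig_genes[1:2], "GENE99"),
                        source = "synthetic_imprinted_catalog")
tags <- tag_imprinted(sig_genes, imprinted)
cat(sprintf("imprinted-gene tags among associated genes: %d (%s)\n",
            nrow(tags), paste(tags$gene_id, collapse = ", ")))
write.table(tags, file.path(OUT_DIR, "imprinted_tags.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
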