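#!/usr/bin/env Rscript
# Expression arm: simulate genes driven by mQTL-associated CpG
# methylation (eQTM chains) and by CNVs directly (eQTLs), run both
# scans with the shared engine, and intersect the mQTL and eQTL CNV
# sets.
source("analysis/00_config.R")

cnvs <- read_matrix(file.path(DATA_DIR, "cnv_genotypes.tsv"), "genotype")
meth <- read_matrix(file.path(DATA_DIR, "methylation_beta.tsv"), "methylation")
mqtl <- read_associations(file.path(OUT_DIR, "mqtl_associations.tsv"))
attr(mqtl, "variant_universe") <- sort(cnvs$intervals$id)
pp <- read.delim(file.path(DATA_DIR, "truth_planted.tsv"))
null_ids <- readLines(file.path(DATA_DIR, "truth_null_cpgs.txt"))

cfg <- study_config()
sig <- call_significant(mqtl, CUTOFF)
sig_cpgs <- intersect(unique(sig$phenotype_id), pp$cpg_id)
plan <- data.frame(gene_id = sprintf("gene%03d", seq_along(sig_cpgs)),
                   driver_type = "methylation", driver_id = sig_cpgs,
                   sign = rep_len(c(-1, 1), length(sig_cpgs)))
cpg_gene <- data.frame(cpg_id = sig_cpgs, gene_id = plan$gene_id)
truth <- synthetic_truth(planted_pairs = pp, null_ids = null_ids,
                         expression_plan = plan)
expr <- simulate_expression(meth, cnvs, truth, cfg, b = 2, noise_sd = 1)
write_matrix(expr, file.path(DATA_DIR, "expression.tsv"))

# eQTM: mQTL-significant CpGs tested against gene expression
sub <- meth
keep <- match(sig_cpgs, sub$intervals$id)
sub$intervals <- sub$intervals[keep, , drop = FALSE]
sub$values <- sub$values[keep, , drop = FALSE]
eqtm <- run_scan(sub, expr, scan_config(scan_kind = "eqtm", n_perm = N_PERM,
                                        seed = SEED + 201L))
write_associations(eqtm, file.path(OUT_DIR, "eqtm_associations.tsv"))
esig <- call_significant(eqtm, CUTOFF)
cat(sprintf("eQTM: %d significant of %d tested (%d positive, %d negative rho)\n",
            nrow(esig), nrow(eqtm), sum(esig$rho > 0), sum(esig$rho < 0)))

# CNV-eQTL scan and the mQTL/eQTL intersection
eqtl <- run_scan(cnvs, expr, scan_config(scan_kind = "cnv-eqtl",
                                         n_perm = N_PERM, seed = SEED + 202L))
write_associations(eqtl, file.path(OUT_DIR, "eqtl_associations.tsv"))
ov <- overlap_mqtl_eqtl(mqtl, eqtl, CUTOFF, cpg_gene = cpg_gene)
cat(sprintf("CNVs that are both mQTL and eQTL: %d; same-gene chains: %d; genes tied to shared CNVs: %d\n",
            length(ov$shared_variants), length(ov$genes_same_both),
            length(ov$genes_expr_assoc)))
writeLines(ov$shared_variants, file.path(OUT_DIR, "shared_mqtl_eqtl_cnvs.txt"))
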