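#!/usr/bin/env Rscript
# Generate the synthetic discovery cohort: CNV genotypes, methylation
# with planted effects, and tag SNPs; write everything as TSV plus the
# ground-truth ledger so later steps can score recovery.
source("analysis/00_config.R")

cfg <- study_config()
cnvs <- simulate_cnv_genotypes(cfg)
truth <- plant_effects(cnvs, cfg, n_planted = 20, targets = 0.5)
meth <- simulate_methylation(cnvs, truth, cfg)

lp <- data.frame(cnv_id = truth$planted_pairs$variant_id,
                 snp_id = sprintf("tag%03d", seq_len(20)),
                 target_r2 = 0.8)
truth$ld_pairs <- lp
snps <- simulate_snps_in_ld(cnvs, truth, cfg)

write_matrix(cnvs, file.path(DATA_DIR, "cnv_genotypes.tsv"))
write_matrix(meth, file.path(DATA_DIR, "methylation_beta.tsv"))
write_matrix(snps, file.path(DATA_DIR, "snp_dosages.tsv"))
write.table(truth$planted_pairs, file.path(DATA_DIR, "truth_planted.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(lp, file.path(DATA_DIR, "truth_ld_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(truth$null_ids, file.path(DATA_DIR, "truth_null_cpgs.txt"))

cat(sprintf("cohort: %d samples, %d CNVs (MAF %.2f-%.2f), %d CpGs (%d planted at |rho|=0.5)\n",
            cfg$n_samples, cfg$n_cnvs, min(genotype_maf(cnvs)),
            max(genotype_maf(cnvs)), cfg$n_cpgs, 20))
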