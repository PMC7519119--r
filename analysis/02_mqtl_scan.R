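#!/usr/bin/env Rscript
# Genome-wide CNV-mQTL scan on the simulated cohort: Spearman tests for
# all proximal (2 Mb window) and distal same-chromosome pairs, 1000
# permutations per CpG, cutoff 0.01; then recovery scoring against the
# truth ledger and the permutation FDR.
source("analysis/00_config.R")

cnvs <- read_matrix(file.path(DATA_DIR, "cnv_genotypes.tsv"), "genotype")
meth <- read_matrix(file.path(DATA_DIR, "methylation_beta.tsv"), "methylation")
pp <- read.delim(file.path(DATA_DIR, "truth_planted.tsv"))
null_ids <- readLines(file.path(DATA_DIR, "truth_null_cpgs.txt"))

rec <- run_scan(cnvs, meth, scan_config(n_perm = N_PERM, seed = SEED + 1L))
write_associations(rec, file.path(OUT_DIR, "mqtl_associations.tsv"))

summ <- summarize_scan(rec, CUTOFF)
cat(sprintf("significant associations: %d (%d proximal, %d distal), %d unique CNVs, %d CpGs, %d both-mode CNVs\n",
            summ$n_associations, summ$n_proximal, summ$n_distal,
            summ$n_unique_variants, summ$n_unique_phenotypes,
            summ$n_both_mode_variants))

key <- paste(rec$variant_id, rec$phenotype_id)
planted <- rec[match(paste(pp$variant_id, pp$cpg_id), key), ]
cat(sprintf("planted-pair recovery at perm p < %.2f: %d/%d (%.0f%%)\n",
            CUTOFF, sum(planted$perm_p < CUTOFF), nrow(pp),
            100 * mean(planted$perm_p < CUTOFF)))

nullrec <- rec[rec$phenotype_id %in% null_ids, ]
fam <- aggregate(perm_p ~ phenotype_id + mode, nullrec, min)
cat(sprintf("null family false-call rate: %.3f (%d families)\n",
            mean(fam$perm_p < CUTOFF), nrow(fam)))

fdr <- estimate_fdr(attr(rec, "n_phenotypes_tested"), CUTOFF,
                    summ$n_unique_phenotypes)
cat(sprintf("permutation FDR: %.1f%%\n", 100 * fdr))

write.table(data.frame(metric = c("n_associations", "n_proximal", "n_distal",
                                  "n_unique_cnvs", "n_cpgs", "recovery",
                                  "null_family_rate", "fdr"),
                       value = c(summ$n_associations, summ$n_proximal,
                                 summ$n_distal, summ$n_unique_variants,
                                 summ$n_unique_phenotypes,
                                 mean(planted$perm_p < CUTOFF),
                                 mean(fam$perm_p < CUTOFF), fdr)),
            file.path(OUT_DIR, "mqtl_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
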