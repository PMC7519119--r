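#!/usr/bin/env Rscript
# Validation-cohort workflow: a smaller independent cohort (n = 24)
# regenerated from the same truth, beta-values quantile-normalized, a
# PCA stratification check, then replication of the discovery
# associations at permutation p < 0.01 and < 0.05.
source("analysis/00_config.R")

cnvs <- read_matrix(file.path(DATA_DIR, "cnv_genotypes.tsv"), "genotype")
disc <- read_associations(file.path(OUT_DIR, "mqtl_associations.tsv"))
attr(disc, "variant_universe") <- sort(cnvs$intervals$id)
pp <- read.delim(file.path(DATA_DIR, "truth_planted.tsv"))
null_ids <- readLines(file.path(DATA_DIR, "truth_null_cpgs.txt"))

cfg_val <- study_config()
cfg_val$seed <- SEED + 101L
cfg_val$n_samples <- 24L
truth <- synthetic_truth(planted_pairs = pp, null_ids = null_ids)
cnvs_val <- cnvs
cnvs_val$values <- cnvs$values[, seq_len(24L), drop = FALSE]
cnvs_val$samples <- cnvs$samples[seq_len(24L)]
meth_val <- simulate_methylation(cnvs_val, truth, cfg_val)
meth_val <- quantile_normalize(meth_val)

pc <- pca_qc(t(meth_val$values), k = 2)
cat(sprintf("PCA check: PC1/PC2 explain %.1f%% / %.1f%% of methylation variance\n",
            100 * pc$explained[1], 100 * pc$explained[2]))

rep <- replicate_scan(disc, cnvs_val, meth_val,
                      scan_config(n_perm = N_PERM, seed = SEED + 102L))
cat(sprintf("replication: %d/%d (%.1f%%) at p < 0.01, %d/%d (%.1f%%) at p < 0.05\n",
            rep$n_replicated_p01, rep$n_tested, 100 * rep$frac_p01,
            rep$n_replicated_p05, rep$n_tested, 100 * rep$frac_p05))
write_associations(rep$records, file.path(OUT_DIR, "validation_associations.tsv"))
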