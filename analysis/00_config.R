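# Shared settings for the analysis workflow. Every script sources this
# file, so the whole chain is reproducible from one seed.
library(cnvmqtl)

SEED <- 20260928L
DATA_DIR <- "results/data"
OUT_DIR <- "results"
dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

# Discovery-cohort geometry at desk scale: 77 samples, 50 CNVs over a
# two-chromosome 5 Mb genome, 220 CpG sites of which 20 carry planted
# effects at |rho| = 0.5, half proximal / half distal.
study_config <- function() {
  sim_config(seed = SEED, n_cnvs = 50, n_cpgs = 220, n_samples = 77,
             n_snps = 60, n_genes = 40)
}

N_PERM <- 1000L
CUTOFF <- 0.01
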