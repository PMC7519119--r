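# Independent oracles, deliberately written without reusing any package
# internals: counting-based average ranks plus the covariance formula
# for Spearman, and the raw summation formula for Pearson.

oracle_avg_rank <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, 0)
}

oracle_spearman <- function(x, y) {
  rx <- oracle_avg_rank(x)
  ry <- oracle_avg_rank(y)
  dx <- rx - sum(rx) / length(rx)
  dy <- ry - sum(ry) / length(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
  num / den
}

# Small synthetic cohort reused across tests: CNVs + methylation with
# planted effects under one config.
small_cohort <- function(seed = 11, n_cnvs = 30, n_cpgs = 40,
                         n_planted = 8, targets = 0.5,
                         n_samples = 77, noise_sd = 1) {
  cfg <- sim_config(seed = seed, n_cnvs = n_cnvs, n_cpgs = n_cpgs,
                    n_samples = n_samples, noise_sd = noise_sd)
  cnvs <- simulate_cnv_genotypes(cfg)
  truth <- plant_effects(cnvs, cfg, n_planted = n_planted,
                         targets = targets)
  meth <- simulate_methylation(cnvs, truth, cfg)
  list(cfg = cfg, cnvs = cnvs, truth = truth, meth = meth)
}

rand_intervals <- function(n, genome, len, seed, prefix = "q") {
  withr::with_seed(seed, {
    chrom <- sample(names(genome), n, replace = TRUE)
    start <- floor(runif(n) * (genome[chrom] - len))
    gintervals(chrom, start, start + len, sprintf("%s%04d", prefix, seq_len(n)))
  })
}
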