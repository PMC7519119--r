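test_that("CNV genotype simulation is seeded, polymorphic, and in range", {
  cfg <- sim_config(seed = 1, n_cnvs = 50, n_samples = 77)
  g1 <- simulate_cnv_genotypes(cfg)
  g2 <- simulate_cnv_genotypes(cfg)
  expect_identical(g1$values, g2$values)
  expect_identical(g1$intervals, g2$intervals)
  expect_true(all(g1$values %in% 0:4))
  # no monomorphic rows
  expect_false(any(apply(g1$values, 1, function(v) length(unique(v)) == 1)))
  expect_true(all(genotype_maf(g1) <= 0.5))
  expect_true(all(g1$intervals$end <= cfg$chrom_lengths[g1$intervals$chrom]))
  expect_error(simulate_cnv_genotypes(sim_config(seed = 1, n_samples = 2)),
               ">= 3")
})

test_that("high-MAF spectra concentrate realized frequencies", {
  cfg <- sim_config(seed = 2, n_cnvs = 40, n_samples = 1000,
                    maf_range = c(0.4, 0.5))
  g <- simulate_cnv_genotypes(cfg)
  # binomial concentration: all realized MAFs >= 0.3 at n = 1000
  expect_true(all(genotype_maf(g) >= 0.3))
})

test_that("planted methylation effects realize their target correlations", {
  # averaged over seeds, realized |rho| tracks the target within 0.15
  for (target in c(0.3, 0.5)) {
    devs <- vapply(1:6, function(s) {
      co <- small_cohort(seed = 100 + s, n_cnvs = 20, n_cpgs = 20,
                         n_planted = 6, targets = target)
      pp <- co$truth$planted_pairs
      mean(vapply(seq_len(nrow(pp)), function(k) {
        abs(rank_correlation(co$cnvs$values[pp$variant_id[k], ],
                             co$meth$values[pp$cpg_id[k], ])$rho)
      }, 0))
    }, 0)
    expect_lt(abs(mean(devs) - target), 0.15)
  }
})

test_that("noise-free planted effects give near-perfect rank correlation", {
  co <- small_cohort(seed = 5, n_cnvs = 10, n_cpgs = 10, n_planted = 4,
                     noise_sd = 0)
  pp <- co$truth$planted_pairs
  for (k in seq_len(nrow(pp))) {
    rho <- rank_correlation(co$cnvs$values[pp$variant_id[k], ],
                            co$meth$values[pp$cpg_id[k], ])$rho
    expect_equal(abs(rho), 1)  # identical tie pattern on both sides
    expect_equal(sign(rho), pp$sign[k])
  }
})

test_that("betas stay in [0,1], nulls stay near the permutation null band", {
  co <- small_cohort(seed = 6, n_cnvs = 20, n_cpgs = 40, n_planted = 0)
  expect_true(all(co$meth$values >= 0 & co$meth$values <= 1))
  # null |rho| < 0.31 ~ 99% of the time at n = 77: allow 2 exceptions in 40
  rhos <- vapply(co$truth$null_ids[1:40], function(id) {
    abs(rank_correlation(co$cnvs$values[1, ], co$meth$values[id, ])$rho)
  }, 0)
  expect_gte(sum(rhos < 0.31), 38L)
})

test_that("planted pairs respect their directed proximal/distal modes", {
  co <- small_cohort(seed = 7, n_cnvs = 30, n_cpgs = 30, n_planted = 10)
  pp <- co$truth$planted_pairs
  cfg_scan <- scan_config()
  for (k in seq_len(nrow(pp))) {
    v <- co$cnvs$intervals[match(pp$variant_id[k], co$cnvs$intervals$id), ]
    s <- co$meth$intervals[match(pp$cpg_id[k], co$meth$intervals$id), ]
    expect_equal(classify_pairing(v, s, cfg_scan), pp$mode[k])
  }
})

test_that("SNPs realize target LD and independents stay uncorrelated", {
  cfg <- sim_config(seed = 8, n_cnvs = 10, n_snps = 20, n_samples = 1000)
  cnvs <- simulate_cnv_genotypes(cfg)
  lp <- data.frame(cnv_id = cnvs$intervals$id[1:4],
                   snp_id = sprintf("tag%02d", 1:4),
                   target_r2 = c(1, 0.8, 0.5, 0.3))
  truth <- synthetic_truth(ld_pairs = lp)
  snps <- simulate_snps_in_ld(cnvs, truth, cfg)
  expect_identical(snps$values, simulate_snps_in_ld(cnvs, truth, cfg)$values)
  for (k in 1:4) {
    r2 <- ld_r2(cnvs$values[lp$cnv_id[k], ], snps$values[lp$snp_id[k], ])
    expect_lt(abs(r2 - lp$target_r2[k]), 0.1)
  }
  expect_equal(ld_r2(cnvs$values[lp$cnv_id[1], ], snps$values["tag01", ]), 1)
  # independent SNP: null r2 ~ 1/n
  expect_lt(ld_r2(cnvs$values[1, ], snps$values["snp0010", ]), 0.05)
  # tagged SNPs placed within 1 Mb of their CNV
  for (k in 1:4) {
    vi <- match(lp$cnv_id[k], cnvs$intervals$id)
    si <- match(lp$snp_id[k], snps$intervals$id)
    expect_equal(snps$intervals$chrom[si], cnvs$intervals$chrom[vi])
    expect_lte(abs(snps$intervals$start[si] -
                     interval_midpoint(cnvs$intervals[vi, ])), 1e6)
  }
})

test_that("expression drivers produce signed monotone effects", {
  co <- small_cohort(seed = 9, n_cnvs = 10, n_cpgs = 10, n_planted = 4)
  plan <- data.frame(
    gene_id = c("geneM", "geneC", "geneN"),
    driver_type = c("methylation", "cnv", "null"),
    driver_id = c(co$truth$planted_pairs$cpg_id[1], co$cnvs$intervals$id[2], NA),
    sign = c(-1, 1, 0))
  truth <- synthetic_truth(planted_pairs = co$truth$planted_pairs,
                           null_ids = co$truth$null_ids,
                           expression_plan = plan)
  co$cfg$noise_sd <- 0
  expr <- simulate_expression(co$meth, co$cnvs, truth, co$cfg, noise_sd = 0)
  expect_true(all(expr$values >= 0))
  expect_equal(rank_correlation(expr$values["geneM", ],
                                co$meth$values[plan$driver_id[1], ])$rho, -1)
  expect_gt(rank_correlation(expr$values["geneC", ],
                             co$cnvs$values[plan$driver_id[2], ])$rho, 0.99)
  bad <- truth; bad$expression_plan$driver_id[1] <- "nope"
  expect_error(simulate_expression(co$meth, co$cnvs, bad, co$cfg),
               "unknown mediator")
})

test_that("feature tracks respect bias and chromosome bounds", {
  cfg <- sim_config(seed = 12)
  roi <- rand_intervals(30, cfg$chrom_lengths, 20000, seed = 13, "roi")
  t1 <- simulate_feature_track(roi, bias = 1, cfg, n_features = 10000,
                               feature_length = 10, name = "uni")
  frac_genome <- sum(roi$end - roi$start) / sum(cfg$chrom_lengths)
  gr_r <- GenomicRanges::GRanges(roi$chrom, IRanges::IRanges(roi$start + 1, roi$end))
  inside <- function(tr) {
    iv <- tr$intervals
    mid <- interval_midpoint(iv)
    mean(GenomicRanges::countOverlaps(
      GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(mid + 1, mid + 1)),
      gr_r) > 0)
  }
  f1 <- inside(t1)
  sd3 <- 3 * sqrt(frac_genome * (1 - frac_genome) / 10000)
  expect_lt(abs(f1 - frac_genome), sd3)
  t10 <- simulate_feature_track(roi, bias = 10, cfg, n_features = 10000,
                                feature_length = 10, name = "hot")
  expect_gt(inside(t10), f1)
  iv <- t10$intervals
  expect_true(all(iv$start >= 0 &
                    iv$end <= cfg$chrom_lengths[iv$chrom]))
  expect_error(simulate_feature_track(roi, bias = 0.5, cfg), ">= 1")
})

test_that("Hi-C simulation plants recoverable high-signal pairs", {
  cfg <- sim_config(seed = 14)
  tp <- data.frame(chrom = "chrA", cnv_start = 1e6, cnv_end = 1.02e6,
                   cpg_start = 1.5e6, cpg_end = 1.501e6, signal = 50)
  truth <- synthetic_truth(hic_true_pairs = tp)
  map <- simulate_hic(truth, 1e4, cfg, chrom = "chrA")
  map2 <- simulate_hic(truth, 1e4, cfg, chrom = "chrA")
  expect_identical(map$entries, map2$entries)
  expect_true(all(map$entries$signal >= 0))
  ps <- pair_signal(list(chrom = "chrA", start = 1e6, end = 1.02e6),
                    list(chrom = "chrA", start = 1.5e6, end = 1.501e6),
                    window_bp = 0, map = map)
  expect_true(ps$nonzero)
  expect_equal(ps$signal, 50)
  # planted signal above the 95th percentile of same-distance background
  d_pair <- 50
  e <- map$entries
  bg <- e$signal[(e$bin2 - e$bin1) == d_pair & e$signal != 50]
  expect_gt(50, quantile(bg, 0.95))
  # background decays with distance (no planted entries in these strata)
  m_near <- mean(e$signal[e$bin2 - e$bin1 >= 1 & e$bin2 - e$bin1 <= 5 &
                            e$signal != 50])
  m_far <- mean(e$signal[e$bin2 - e$bin1 >= 100 & e$signal != 50])
  expect_gt(m_near, m_far)
  bad <- truth
  bad$hic_true_pairs$cpg_start <- 9e6; bad$hic_true_pairs$cpg_end <- 9.01e6
  expect_error(simulate_hic(bad, 1e4, cfg, chrom = "chrA"), "off the chromosome")
})
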