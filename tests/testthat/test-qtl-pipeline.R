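test_that("pair classification follows the 2 Mb window convention", {
  cfg <- scan_config()
  cpg <- list(chrom = "chr1", start = 1999500, end = 2000500)  # midpoint 2 Mb
  expect_equal(classify_pairing(list(chrom = "chr1", start = 1500000,
                                     end = 1600000), cpg, cfg), "proximal")
  expect_equal(classify_pairing(list(chrom = "chr1", start = 8000000,
                                     end = 8050000), cpg, cfg), "distal")
  expect_equal(classify_pairing(list(chrom = "chr2", start = 2000000,
                                     end = 2100000), cpg, cfg), "untested")
  # >= 1 bp overlap with [mid - 1 Mb, mid + 1 Mb) decides membership,
  # so a window-straddling CNV is proximal even if its midpoint is outside
  expect_equal(classify_pairing(list(chrom = "chr1", start = 900000,
                                     end = 1000001), cpg, cfg), "proximal")
  expect_equal(classify_pairing(list(chrom = "chr1", start = 900000,
                                     end = 1000000), cpg, cfg), "distal")
  # mode labels are stable under a constant coordinate shift
  sh <- 12345
  expect_equal(
    classify_pairing(list(chrom = "chr1", start = 1500000 + sh,
                          end = 1600000 + sh),
                     list(chrom = "chr1", start = 1999500 + sh,
                          end = 2000500 + sh), cfg),
    "proximal")
})

test_that("run_scan recovers a noise-free planted pair at the floor", {
  co <- small_cohort(seed = 31, n_cnvs = 15, n_cpgs = 10, n_planted = 3,
                     noise_sd = 0)
  rec <- run_scan(co$cnvs, co$meth, scan_config(n_perm = 150, seed = 2))
  pp <- co$truth$planted_pairs
  key <- paste(rec$variant_id, rec$phenotype_id)
  hit <- rec[match(paste(pp$variant_id, pp$cpg_id), key), ]
  expect_equal(abs(hit$rho), rep(1, 3))
  expect_equal(hit$perm_p, rep(1 / 151, 3))
  expect_equal(hit$mode, pp$mode)
})

test_that("run_scan partitions candidates and reports signed distances", {
  co <- small_cohort(seed = 32, n_cnvs = 20, n_cpgs = 8, n_planted = 2)
  rec <- run_scan(co$cnvs, co$meth, scan_config(n_perm = 100, seed = 3))
  # every same-chromosome pair appears exactly once, as proximal or distal
  for (i in seq_len(nrow(co$meth$intervals))) {
    s <- co$meth$intervals[i, ]
    same <- co$cnvs$intervals$chrom == s$chrom
    expect_equal(sum(rec$phenotype_id == s$id), sum(same))
  }
  # distance = variant midpoint - phenotype midpoint
  r1 <- rec[1, ]
  v <- co$cnvs$intervals[match(r1$variant_id, co$cnvs$intervals$id), ]
  s <- co$meth$intervals[match(r1$phenotype_id, co$meth$intervals$id), ]
  expect_equal(r1$distance, interval_midpoint(v) - interval_midpoint(s))
  # determinism: identical reruns, byte-identical written tables
  rec2 <- run_scan(co$cnvs, co$meth, scan_config(n_perm = 100, seed = 3))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_associations(rec, f1); write_associations(rec2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("scan summaries count modes, uniques, and both-mode variants", {
  rec <- data.frame(
    variant_id = c("v1", "v1", "v2", "v3"),
    phenotype_id = c("c1", "c2", "c3", "c4"),
    mode = c("proximal", "distal", "proximal", "distal"),
    distance = c(5e5, 3e6, -2e5, 8e6),
    rho = 0.5, nominal_p = 1e-4,
    perm_p = c(0.001, 0.005, 0.002, 0.5))
  s <- summarize_scan(rec, threshold = 0.01)
  expect_equal(s$n_associations, 3L)
  expect_equal(s$n_proximal, 2L)
  expect_equal(s$n_distal, 1L)
  expect_equal(s$n_unique_variants, 2L)
  expect_equal(s$n_unique_phenotypes, 3L)
  expect_equal(s$n_both_mode_variants, 1L)
  expect_equal(sum(s$distance_histogram$count), 3L)
  s0 <- summarize_scan(rec[rec$perm_p > 0.4, ], threshold = 0.01)
  expect_equal(s0$n_associations, 0L)
  expect_equal(s0$n_both_mode_variants, 0L)
})

test_that("mQTL/eQTL overlap joins shared CNVs and same-gene chains", {
  mk <- function(v, p, pp, universe) {
    r <- data.frame(variant_id = v, phenotype_id = p,
                    mode = "proximal", distance = 0, rho = 0.5,
                    nominal_p = 1e-4, perm_p = pp)
    attr(r, "variant_universe") <- universe
    r
  }
  uni <- c("v1", "v2", "v3")
  mqtl <- mk(c("v1", "v2"), c("cpgA", "cpgB"), c(0.001, 0.001), uni)
  eqtl <- mk(c("v1", "v3"), c("geneA", "geneB"), c(0.001, 0.001), uni)
  map <- data.frame(cpg_id = c("cpgA", "cpgB"), gene_id = c("geneA", "geneZ"))
  ov <- overlap_mqtl_eqtl(mqtl, eqtl, 0.01, cpg_gene = map)
  expect_equal(ov$shared_variants, "v1")
  expect_equal(ov$genes_same_both, "geneA")
  expect_equal(ov$genes_expr_assoc, "geneA")
  # disjoint significant sets -> empty report
  ov2 <- overlap_mqtl_eqtl(mk("v1", "cpgA", 0.001, uni),
                           mk("v2", "geneA", 0.001, uni), 0.01, map)
  expect_equal(length(ov2$shared_variants), 0L)
  expect_error(overlap_mqtl_eqtl(mqtl, mk("v1", "geneA", 0.001, c("v9")), 0.01),
               "different variant universes")
})

test_that("a planted mediation chain is recovered end to end", {
  co <- small_cohort(seed = 33, n_cnvs = 12, n_cpgs = 12, n_planted = 3,
                     targets = 0.8)
  pp <- co$truth$planted_pairs
  plan <- data.frame(
    gene_id = c("gene1", "gene2", "geneNull"),
    driver_type = c("methylation", "methylation", "null"),
    driver_id = c(pp$cpg_id[1:2], NA),
    sign = c(-1, 1, 0))
  truth <- synthetic_truth(planted_pairs = pp, null_ids = co$truth$null_ids,
                           expression_plan = plan)
  expr <- simulate_expression(co$meth, co$cnvs, truth, co$cfg, b = 3,
                              noise_sd = 0.1)
  cfgs <- scan_config(n_perm = 300, seed = 4)
  mqtl <- run_scan(co$cnvs, co$meth, cfgs)
  eqtl <- run_scan(co$cnvs, expr, scan_config(scan_kind = "cnv-eqtl",
                                              n_perm = 300, seed = 5))
  map <- data.frame(cpg_id = pp$cpg_id[1:2], gene_id = c("gene1", "gene2"))
  ov <- overlap_mqtl_eqtl(mqtl, eqtl, 0.01, cpg_gene = map)
  expect_true(all(c("gene1", "gene2") %in% ov$genes_same_both))
})

test_that("eQTM reuse of the engine tests CpG rows against expression", {
  co <- small_cohort(seed = 34, n_cnvs = 8, n_cpgs = 10, n_planted = 2,
                     targets = 0.9)
  pp <- co$truth$planted_pairs
  plan <- data.frame(gene_id = "g1", driver_type = "methylation",
                     driver_id = pp$cpg_id[1], sign = -1)
  truth <- synthetic_truth(planted_pairs = pp, null_ids = co$truth$null_ids,
                           expression_plan = plan)
  expr <- simulate_expression(co$meth, co$cnvs, truth, co$cfg, b = 3,
                              noise_sd = 0)
  # restrict tested CpGs to the mQTL-significant set, then scan genes
  sub <- co$meth
  keep <- match(pp$cpg_id, sub$intervals$id)
  sub$intervals <- sub$intervals[keep, ]
  sub$values <- sub$values[keep, , drop = FALSE]
  rec <- run_scan(sub, expr, scan_config(scan_kind = "eqtm",
                                         n_perm = 200, seed = 6))
  hit <- rec[rec$variant_id == pp$cpg_id[1] & rec$phenotype_id == "g1", ]
  expect_equal(nrow(hit), 1L)
  expect_lt(hit$rho, -0.9)
  expect_lt(hit$perm_p, 0.01)
})

test_that("replication re-tests discovery pairs at both cutoffs", {
  co <- small_cohort(seed = 35, n_cnvs = 15, n_cpgs = 12, n_planted = 4,
                     targets = 0.9)
  disc <- run_scan(co$cnvs, co$meth, scan_config(n_perm = 200, seed = 7))
  # validation cohort: same truth, fresh noise via a different seed
  cfg2 <- co$cfg; cfg2$seed <- 77L
  meth2 <- simulate_methylation(co$cnvs, co$truth, cfg2)
  rep <- replicate_scan(disc, co$cnvs, meth2,
                        scan_config(n_perm = 200, seed = 8))
  expect_gte(rep$n_tested, 4L)
  expect_gte(rep$frac_p05, rep$frac_p01)
  expect_gte(rep$frac_p05, 0.5)  # strong planted effects replicate
  expect_error(replicate_scan(disc[disc$perm_p > 0.9, ], co$cnvs, meth2),
               "no discovery-significant")
})
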