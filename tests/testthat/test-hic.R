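test_that("interval-to-bin mapping uses floor arithmetic on half-open input", {
  expect_equal(interval_to_bins(list(start = 25000, end = 26000), 1e4), 2)
  expect_equal(interval_to_bins(list(start = 9999, end = 10001), 1e4), c(0, 1))
  expect_equal(interval_to_bins(list(start = 0, end = 10000), 1e4), 0)
  expect_error(interval_to_bins(list(start = 5, end = 5), 1e4), "empty")
  expect_error(interval_to_bins(list(start = 0, end = 10), 0), "> 0")
})

test_that("pair signal looks up the sparse map symmetrically with max aggregation", {
  ent <- data.frame(bin1 = c(2, 5, 10), bin2 = c(8, 5, 12),
                    signal = c(3.5, 1.0, 7.0))
  map <- hic_map(ent, resolution = 1e4, chrom = "chrA", n_bins = 50)
  cnv <- list(chrom = "chrA", start = 20000, end = 30000)   # bin 2
  cpg <- list(chrom = "chrA", start = 80000, end = 81000)   # bin 8
  ps <- pair_signal(cnv, cpg, window_bp = 0, map = map)
  expect_true(ps$nonzero)
  expect_equal(ps$signal, 3.5)
  # symmetric access: roles swapped, same entry
  expect_equal(pair_signal(cpg, cnv, 0, map)$signal, 3.5)
  # absent entries mean zero
  far <- list(chrom = "chrA", start = 400000, end = 401000)
  expect_false(pair_signal(cnv, far, 0, map)$nonzero)
  # widening the CpG window never decreases the signal
  near <- list(chrom = "chrA", start = 60000, end = 61000)  # bin 6
  s2k <- pair_signal(cnv, near, 2000, map)$signal
  s25k <- pair_signal(cnv, near, 25000, map)$signal
  expect_gte(s25k, s2k)
  expect_equal(s25k, 3.5)  # window reaches bin 8
  expect_error(pair_signal(list(chrom = "chrB", start = 0, end = 10),
                           cpg, 0, map), "intra-chromosomal")
})

test_that("contact maps round-trip through the 3-column TSV", {
  ent <- data.frame(bin1 = c(0, 3), bin2 = c(4, 9), signal = c(2.5, 0.5))
  map <- hic_map(ent, 1e4, "chrA", 20)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_contacts(map, p)
  back <- read_contacts(p, 1e4, "chrA", 2e5)
  expect_equal(back$entries, map$entries)
  expect_equal(back$n_bins, map$n_bins)
})

test_that("matched pair sampling preserves length and distance multisets", {
  genome <- c(chrA = 5e6)
  withr::with_seed(81, {
    cnv_start <- floor(runif(25) * 4e6)
    cnv_len <- sample(c(5000, 20000, 80000), 25, replace = TRUE)
    cpg_len <- sample(c(1000, 2000), 25, replace = TRUE)
    off <- sample(c(-1, 1), 25, TRUE) * floor(runif(25, 2e5, 8e5))
  })
  pairs <- data.frame(chrom = "chrA", cnv_start = cnv_start,
                      cnv_end = cnv_start + cnv_len,
                      cpg_start = pmax(0, cnv_start + off),
                      cpg_end = pmax(0, cnv_start + off) + cpg_len)
  r <- sample_matched_pairs(pairs, genome, seed = 82)
  expect_equal(sort(r$cnv_end - r$cnv_start), sort(cnv_len))
  expect_equal(sort(r$cpg_end - r$cpg_start), sort(cpg_len))
  mid <- function(a, b) floor((a + b) / 2)
  d_obs <- sort(abs(mid(pairs$cnv_start, pairs$cnv_end) -
                      mid(pairs$cpg_start, pairs$cpg_end)))
  d_new <- sort(abs(mid(r$cnv_start, r$cnv_end) - mid(r$cpg_start, r$cpg_end)))
  expect_true(all(abs(d_obs - d_new) <= 1e4))  # +/- 1 bin at 10 kb
  expect_true(all(r$cnv_start >= 0 & r$cnv_end <= genome["chrA"] &
                    r$cpg_start >= 0 & r$cpg_end <= genome["chrA"]))
  expect_identical(sample_matched_pairs(pairs, genome, seed = 82), r)
  big <- data.frame(chrom = "chrA", cnv_start = 0, cnv_end = 1000,
                    cpg_start = 5.9e6, cpg_end = 5.9e6 + 1000)
  expect_error(sample_matched_pairs(big, genome, seed = 1), "exceeds")
})

test_that("the Hi-C permutation test hits the floor on planted pairs", {
  cfg <- sim_config(seed = 83)
  tp <- data.frame(chrom = "chrA",
                   cnv_start = seq(1e5, 4.2e6, length.out = 15))
  tp$cnv_end <- tp$cnv_start + 2e4
  tp$cpg_start <- tp$cnv_start + 5e5
  tp$cpg_end <- tp$cpg_start + 1e3
  tp$signal <- 50
  truth <- synthetic_truth(hic_true_pairs = tp)
  map <- simulate_hic(truth, 1e4, cfg, chrom = "chrA", density = 0.5)
  pairs <- tp[, c("chrom", "cnv_start", "cnv_end", "cpg_start", "cpg_end")]
  h <- hic_permutation_test(pairs, map, window_bp = 5000,
                            iterations = 300, seed = 84)
  expect_equal(h$observed, 15L)
  expect_equal(h$p_enrich, 1 / 301)
  # log-ratio summary is consistent with the tail p-value
  expect_gt(median(h$log_ratios), 0)
  expect_equal(h$log_ratios, log((h$observed + 1) / (h$null_counts + 1)))
  # the observed statistic is invariant to pair ordering
  h2 <- hic_permutation_test(pairs[rev(seq_len(nrow(pairs))), ], map,
                             window_bp = 5000, iterations = 100, seed = 84)
  expect_equal(h2$observed, h$observed)
  expect_error(hic_permutation_test(pairs[0, ], map), "empty pair")
})

test_that("proximal planted contacts score above distal pairs", {
  cfg <- sim_config(seed = 85)
  prox <- data.frame(chrom = "chrA",
                     cnv_start = seq(2e5, 2e6, length.out = 8))
  prox$cnv_end <- prox$cnv_start + 1e4
  prox$cpg_start <- prox$cnv_start + 3e5   # within the 1 Mb window
  prox$cpg_end <- prox$cpg_start + 1e3
  prox$signal <- 40
  truth <- synthetic_truth(hic_true_pairs = prox)
  map <- simulate_hic(truth, 1e4, cfg, chrom = "chrA", density = 0.5)
  sig_of <- function(df) vapply(seq_len(nrow(df)), function(j) {
    pair_signal(list(chrom = "chrA", start = df$cnv_start[j],
                     end = df$cnv_end[j]),
                list(chrom = "chrA", start = df$cpg_start[j],
                     end = df$cpg_end[j]), 5000, map)$signal
  }, 0)
  distal <- prox
  distal$cpg_start <- prox$cnv_start + 2.5e6
  distal$cpg_end <- distal$cpg_start + 1e3
  ok <- distal$cpg_end <= 5e6
  expect_gt(median(sig_of(prox)), median(sig_of(distal[ok, ])))
})
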