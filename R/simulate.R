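#' Simulation configuration
#'
#' Settings shared by the synthetic cohort generators. Defaults emulate
#' the discovery-cohort geometry at desk scale: 77 samples, a common-CNV
#' allele-frequency spectrum (MAF 0.05-0.5), and a two-chromosome 5 Mb
#' toy genome so that both proximal (within 1 Mb of a CpG midpoint) and
#' distal placements exist. One global seed fans out into independent
#' per-generator streams, so each matrix can be regenerated on its own.
#'
#' @param n_samples cohort size (>= 3).
#' @param n_cnvs,n_cpgs,n_snps,n_genes row counts for the generated
#'   matrices.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param effect_grid planted |rho| targets, each in (0, 1].
#' @param noise_sd latent noise standard deviation for planted
#'   methylation effects (the effect slope is calibrated against it).
#' @param cnv_size_range,cpg_size_range interval length ranges in bp
#'   (CNV lengths drawn log-uniform).
#' @param seed integer seed (mandatory).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 77L, n_cnvs = 50L, n_cpgs = 200L,
                       n_snps = 50L, n_genes = 50L,
                       chrom_lengths = c(chrA = 5e6, chrB = 5e6),
                       maf_range = c(0.05, 0.5),
                       effect_grid = c(0.3, 0.4, 0.5),
                       noise_sd = 1,
                       cnv_size_range = c(1e3, 1e5),
                       cpg_size_range = c(200, 1500),
                       seed = NULL) {
  if (is.null(seed)) stop("sim_config requires an explicit seed", call. = FALSE)
  counts <- c(n_samples, n_cnvs, n_cpgs, n_snps, n_genes)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_cnvs = as.integer(n_cnvs), n_cpgs = as.integer(n_cpgs),
                 n_snps = as.integer(n_snps), n_genes = as.integer(n_genes),
                 chrom_lengths = chrom_lengths, maf_range = maf_range,
                 effect_grid = effect_grid, noise_sd = noise_sd,
                 cnv_size_range = cnv_size_range,
                 cpg_size_range = cpg_size_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Ground-truth ledger for planted effects
#'
#' Records everything the generators plant, so recovery can be scored:
#' CNV-CpG effect pairs (sign, target |rho|, intended proximal/distal
#' mode), null CpG ids, CNV-SNP LD pairs with target r-squared,
#' biased-placement feature tracks, expression driver assignments, and
#' high-signal Hi-C anchor pairs.
#'
#' @param planted_pairs data frame `(variant_id, cpg_id, sign,
#'   target_rho, mode)`.
#' @param null_ids phenotype ids carrying no planted effect (disjoint
#'   from planted cpg ids).
#' @param ld_pairs data frame `(cnv_id, snp_id, target_r2)`.
#' @param enriched_tracks data frame `(track_name, bias)`.
#' @param expression_plan data frame `(gene_id, driver_type, driver_id,
#'   sign)` with `driver_type` one of methylation/cnv/null.
#' @param hic_true_pairs data frame of anchor intervals `(chrom,
#'   cnv_start, cnv_end, cpg_start, cpg_end, signal)`.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(planted_pairs = NULL, null_ids = character(),
                            ld_pairs = NULL, enriched_tracks = NULL,
                            expression_plan = NULL, hic_true_pairs = NULL) {
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("variant_id", "cpg_id", "sign", "target_rho", "mode")
                  %in% names(planted_pairs)))
    if (any(planted_pairs$target_rho <= 0 | planted_pairs$target_rho > 1))
      stop("target |rho| must lie in (0, 1]", call. = FALSE)
    if (length(intersect(planted_pairs$cpg_id, null_ids)) > 0L)
      stop("planted and null phenotype ids must be disjoint", call. = FALSE)
  }
  if (!is.null(ld_pairs) &&
      any(ld_pairs$target_r2 < 0 | ld_pairs$target_r2 > 1))
    stop("target r2 must lie in [0, 1]", call. = FALSE)
  structure(list(planted_pairs = planted_pairs, null_ids = null_ids,
                 ld_pairs = ld_pairs, enriched_tracks = enriched_tracks,
                 expression_plan = expression_plan,
                 hic_true_pairs = hic_true_pairs),
            class = "synthetic_truth")
}

#' Simulate CNV genotypes
#'
#' Draws integer copy-number states in \{0..4\}: each variant gets a MAF
#' from `cfg$maf_range`, a random orientation (deletion states 2,1,0 or
#' duplication states 2,3,4), and per-sample non-reference allele counts
#' Binomial(2, MAF). Monomorphic draws are redrawn so every variant is
#' polymorphic in the sample. Intervals are placed uniformly with
#' log-uniform lengths.
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_cnv_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_samples < 3L)
    stop("n_samples must be >= 3 for downstream correlation", call. = FALSE)
  withr::with_seed(sub_seed(cfg$seed, "cnv"), {
    n <- cfg$n_samples
    chrom <- sample(names(cfg$chrom_lengths), cfg$n_cnvs, replace = TRUE)
    len <- round(exp(stats::runif(cfg$n_cnvs, log(cfg$cnv_size_range[1]),
                                  log(cfg$cnv_size_range[2]))))
    start <- floor(stats::runif(cfg$n_cnvs) *
                     (cfg$chrom_lengths[chrom] - len))
    iv <- gintervals(chrom, start, start + len,
                     sprintf("cnv%04d", seq_len(cfg$n_cnvs)))
    vals <- matrix(0L, cfg$n_cnvs, n)
    for (i in seq_len(cfg$n_cnvs)) {
      maf <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
      dir <- sample(c(-1L, 1L), 1L)
      repeat {
        dos <- stats::rbinom(n, 2L, maf)
        if (length(unique(dos)) > 1L) break
      }
      vals[i, ] <- 2L + dir * dos
    }
    genotype_matrix(iv, sprintf("s%03d", seq_len(n)), vals)
  })
}

#' Plant CNV-CpG effects
#'
#' Chooses which CNVs drive which CpGs, cycling the target |rho| grid
#' with alternating signs and alternating proximal/distal placement
#' directives; remaining CpG ids become the planted-null set.
#'
#' @param cnvs a [genotype_matrix()] of CNVs.
#' @param cfg a [sim_config()].
#' @param n_planted number of planted pairs (<= min(n_cnvs, n_cpgs)).
#' @param targets target |rho| magnitudes, recycled over pairs.
#' @param modes intended pairing modes, recycled.
#' @return A [synthetic_truth()] with `planted_pairs` and `null_ids`.
#' @export
plant_effects <- function(cnvs, cfg, n_planted = 20L,
                          targets = cfg$effect_grid,
                          modes = c("proximal", "distal")) {
  stopifnot(n_planted <= cfg$n_cpgs, n_planted <= nrow(cnvs$intervals))
  withr::with_seed(sub_seed(cfg$seed, "plant"), {
    vid <- sample(cnvs$intervals$id, n_planted)
    cpg_ids <- sprintf("cpg%04d", seq_len(cfg$n_cpgs))
    planted <- data.frame(
      variant_id = vid,
      cpg_id = cpg_ids[seq_len(n_planted)],
      sign = rep_len(c(1, -1), n_planted),
      target_rho = rep_len(targets, n_planted),
      mode = rep_len(modes, n_planted),
      stringsAsFactors = FALSE
    )
    synthetic_truth(planted_pairs = planted,
                    null_ids = setdiff(cpg_ids, planted$cpg_id))
  })
}

# Empirical effect calibration: the planted model is
# beta = plogis(a * state + noise), and Spearman(state, beta) depends
# only on the signal-to-noise slope a. The paper's observational data
# give no generative model, so a is calibrated by pilot simulation: the
# expected |rho| is estimated on a log-spaced slope grid with common
# random noise, then inverted by monotone interpolation.
calibrate_effect_slope <- function(states, target_rho, noise_sd,
                                   n_draws = 120L) {
  if (noise_sd <= 0) return(1)
  zs <- zrank(states)
  n <- length(states)
  grid <- exp(seq(log(0.02), log(30), length.out = 30L))
  eps <- matrix(stats::rnorm(n * n_draws, sd = noise_sd), n_draws, n,
                byrow = FALSE)
  f <- vapply(grid, function(a) {
    mean(apply(eps, 1L, function(e) {
      sum(zrank(a * states + e) * zs) / (n - 1)
    }))
  }, 0)
  f <- cummax(f)
  if (target_rho >= max(f)) return(max(grid))
  if (target_rho <= min(f)) return(min(grid))
  stats::approx(f, grid, xout = target_rho, ties = "ordered")$y
}

#' Simulate CpG methylation with planted CNV effects
#'
#' Planted CpGs follow `beta = plogis(sign * a * state + noise)` with
#' the slope `a` calibrated per pair so the expected Spearman |rho|
#' tracks the target magnitude; null CpGs are logistic-transformed
#' Gaussian noise around a per-site baseline. CpG coordinates are
#' placed so each planted pair realizes its directed proximal/distal
#' mode (midpoint within ~0.5 Mb of the CNV midpoint, or beyond the
#' 1 Mb window plus the CNV extent, respectively); null CpGs are placed
#' uniformly.
#'
#' @param cnvs a [genotype_matrix()] of CNVs.
#' @param truth a [synthetic_truth()] with `planted_pairs`/`null_ids`.
#' @param cfg a [sim_config()].
#' @return A [methylation_matrix()] whose rows are the planted CpGs
#'   followed by the null CpGs.
#' @export
simulate_methylation <- function(cnvs, truth, cfg) {
  stopifnot(inherits(truth, "synthetic_truth"))
  pp <- truth$planted_pairs
  if (!is.null(pp)) {
    if (!all(pp$variant_id %in% cnvs$intervals$id))
      stop("planted pair references unknown variant id", call. = FALSE)
    if (any(abs(pp$target_rho) > 1))
      stop("effect magnitude must not exceed 1", call. = FALSE)
  }
  withr::with_seed(sub_seed(cfg$seed, "meth"), {
    n <- cfg$n_samples
    ids <- c(pp$cpg_id, truth$null_ids)
    stopifnot(length(ids) == cfg$n_cpgs)
    chrom <- character(cfg$n_cpgs)
    mid <- numeric(cfg$n_cpgs)
    len <- round(stats::runif(cfg$n_cpgs, cfg$cpg_size_range[1],
                              cfg$cpg_size_range[2]))
    beta <- matrix(NA_real_, cfg$n_cpgs, n)
    w <- 1e6
    np <- if (is.null(pp)) 0L else nrow(pp)
    for (k in seq_len(np)) {
      vi <- match(pp$variant_id[k], cnvs$intervals$id)
      vint <- cnvs$intervals[vi, ]
      vmid <- interval_midpoint(vint)
      L <- cfg$chrom_lengths[[vint$chrom]]
      chrom[k] <- vint$chrom
      if (pp$mode[k] == "proximal") {
        mid[k] <- round(min(max(vmid + stats::runif(1, -w / 2, w / 2),
                                len[k]), L - len[k]))
      } else {
        vlen <- vint$end - vint$start
        gap <- w + vlen / 2 + 1e4 + stats::runif(1, 0, 1e6)
        cand <- c(vmid - gap, vmid + gap)
        ok <- cand > len[k] & cand < L - len[k]
        if (!any(ok))
          stop("chromosome too short for a distal placement", call. = FALSE)
        mid[k] <- round(cand[ok][sample.int(sum(ok), 1L)])
      }
      state <- cnvs$values[vi, ]
      a <- calibrate_effect_slope(state, pp$target_rho[k], cfg$noise_sd)
      latent <- pp$sign[k] * a * (state - mean(state)) +
        stats::rnorm(n, sd = cfg$noise_sd)
      beta[k, ] <- stats::plogis(latent)
    }
    for (k in seq.int(np + 1L, length.out = cfg$n_cpgs - np)) {
      chrom[k] <- sample(names(cfg$chrom_lengths), 1L)
      L <- cfg$chrom_lengths[[chrom[k]]]
      mid[k] <- round(stats::runif(1, len[k], L - len[k]))
      base <- stats::rnorm(1)
      beta[k, ] <- stats::plogis(base + stats::rnorm(n, sd = cfg$noise_sd))
    }
    start <- pmax(0, round(mid - len / 2))
    iv <- gintervals(chrom, start, start + len, ids)
    methylation_matrix(iv, cnvs$samples[seq_len(n)], beta)
  })
}

#' Simulate SNP dosages in tunable LD with CNVs
#'
#' For each truth `ld_pair`, the SNP dosage starts as the CNV's
#' non-reference allele dosage (`min(2, |state - 2|)`, a monotone
#' recoding) and entries are then replaced at a calibrated rate
#' (`1 - sqrt(target r2)`) by independent draws from the marginal, so
#' the realized r-squared tracks the target (tolerance ~0.1 at n >= 77).
#' Remaining SNPs are independent Binomial(2, MAF) draws. Tagged SNPs
#' are placed within 1 Mb of their paired CNV; the rest uniformly.
#'
#' @param cnvs a [genotype_matrix()] of CNVs.
#' @param truth a [synthetic_truth()]; `ld_pairs` may be `NULL`.
#' @param cfg a [sim_config()].
#' @return A [genotype_matrix()] of SNP dosages (0/1/2).
#' @export
simulate_snps_in_ld <- function(cnvs, truth, cfg) {
  lp <- truth$ld_pairs
  if (!is.null(lp) && !all(lp$cnv_id %in% cnvs$intervals$id))
    stop("ld pair references unknown CNV id", call. = FALSE)
  withr::with_seed(sub_seed(cfg$seed, "snp"), {
    n <- cfg$n_samples
    nl <- if (is.null(lp)) 0L else nrow(lp)
    stopifnot(cfg$n_snps >= nl)
    ids <- character(cfg$n_snps)
    chrom <- character(cfg$n_snps)
    pos <- numeric(cfg$n_snps)
    vals <- matrix(0L, cfg$n_snps, n)
    for (k in seq_len(nl)) {
      vi <- match(lp$cnv_id[k], cnvs$intervals$id)
      dos <- pmin(2L, abs(cnvs$values[vi, ] - 2L))
      if (length(unique(dos)) == 1L)
        stop("cannot realize target r2: recoded CNV dosage is constant",
             call. = FALSE)
      flip <- 1 - sqrt(lp$target_r2[k])
      snp <- dos
      if (flip > 0) {
        hit <- stats::runif(n) < flip
        snp[hit] <- sample(dos, sum(hit), replace = TRUE)
      }
      vals[k, ] <- snp
      ids[k] <- lp$snp_id[k]
      vint <- cnvs$intervals[vi, ]
      chrom[k] <- vint$chrom
      L <- cfg$chrom_lengths[[vint$chrom]]
      pos[k] <- round(min(max(interval_midpoint(vint) +
                                stats::runif(1, -9e5, 9e5), 0), L - 2))
    }
    for (k in seq.int(nl + 1L, length.out = cfg$n_snps - nl)) {
      maf <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
      repeat {
        dos <- stats::rbinom(n, 2L, maf)
        if (length(unique(dos)) > 1L) break
      }
      vals[k, ] <- dos
      ids[k] <- sprintf("snp%04d", k)
      chrom[k] <- sample(names(cfg$chrom_lengths), 1L)
      pos[k] <- floor(stats::runif(1) * (cfg$chrom_lengths[[chrom[k]]] - 1))
    }
    iv <- gintervals(chrom, pos, pos + 1, ids)
    genotype_matrix(iv, cnvs$samples[seq_len(n)], vals)
  })
}

#' Simulate gene expression with planted drivers
#'
#' Genes are methylation-driven (monotone in a named CpG's beta, either
#' sign), CNV-driven, or null, per `truth$expression_plan`; values are
#' `exp(sign * b * z(driver) + noise)`, hence non-negative and, at zero
#' noise, perfectly rank-correlated with the driver. Gene intervals are
#' placed near their driver (methylation/CNV) or uniformly (null).
#'
#' @param meth a [methylation_matrix()].
#' @param cnvs a [genotype_matrix()].
#' @param truth a [synthetic_truth()] with `expression_plan`.
#' @param cfg a [sim_config()].
#' @param b effect slope on the standardized driver.
#' @param noise_sd expression noise standard deviation on the log scale.
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(meth, cnvs, truth, cfg, b = 1,
                                noise_sd = cfg$noise_sd) {
  plan <- truth$expression_plan
  if (is.null(plan)) stop("truth carries no expression plan", call. = FALSE)
  bad <- plan$driver_type == "methylation" & !(plan$driver_id %in% meth$intervals$id) |
    plan$driver_type == "cnv" & !(plan$driver_id %in% cnvs$intervals$id)
  if (any(bad)) stop("unknown mediator id in expression plan", call. = FALSE)
  withr::with_seed(sub_seed(cfg$seed, "expr"), {
    n <- cfg$n_samples
    ng <- nrow(plan)
    chrom <- character(ng)
    mid <- numeric(ng)
    vals <- matrix(0, ng, n)
    for (k in seq_len(ng)) {
      type <- plan$driver_type[k]
      if (type == "methylation") {
        i <- match(plan$driver_id[k], meth$intervals$id)
        drv <- meth$values[i, ]
        anchor <- meth$intervals[i, ]
      } else if (type == "cnv") {
        i <- match(plan$driver_id[k], cnvs$intervals$id)
        drv <- cnvs$values[i, ]
        anchor <- cnvs$intervals[i, ]
      } else {
        drv <- NULL
        anchor <- NULL
      }
      if (is.null(drv)) {
        chrom[k] <- sample(names(cfg$chrom_lengths), 1L)
        mid[k] <- round(stats::runif(1, 5e3, cfg$chrom_lengths[[chrom[k]]] - 5e3))
        lat <- stats::rnorm(n, sd = max(noise_sd, 0.5))
      } else {
        chrom[k] <- anchor$chrom
        L <- cfg$chrom_lengths[[anchor$chrom]]
        mid[k] <- round(min(max(interval_midpoint(anchor) +
                                  stats::runif(1, -5e5, 5e5), 5e3), L - 5e3))
        z <- (drv - mean(drv)) / max(stats::sd(drv), .Machine$double.eps)
        lat <- plan$sign[k] * b * z + stats::rnorm(n, sd = noise_sd)
      }
      vals[k, ] <- exp(lat)
    }
    iv <- gintervals(chrom, pmax(0, mid - 2500), pmax(0, mid - 2500) + 5000,
                     plan$gene_id)
    expression_matrix(iv, cnvs$samples[seq_len(n)], vals)
  })
}

#' Simulate a feature track with placement bias
#'
#' Places fixed-length features on the genome; probability mass inside
#' `regions_of_interest` is multiplied by `bias` and renormalized, so
#' `bias = 1` is uniform and larger values concentrate features in the
#' regions (planted enrichment). Placement is by feature midpoint.
#'
#' @param regions_of_interest interval table (may be empty with
#'   `bias = 1`).
#' @param bias placement bias factor (>= 1).
#' @param cfg a [sim_config()] (supplies genome and seed).
#' @param n_features number of features.
#' @param feature_length feature length in bp.
#' @param name track label.
#' @param seed optional seed override (defaults to the cfg stream).
#' @return A [feature_track()].
#' @export
simulate_feature_track <- function(regions_of_interest, bias, cfg,
                                   n_features = 1000L, feature_length = 500L,
                                   name = "track", seed = NULL) {
  if (bias < 1) stop("bias must be >= 1", call. = FALSE)
  genome <- cfg$chrom_lengths
  if (length(genome) == 0L || sum(genome) <= 0)
    stop("empty genome", call. = FALSE)
  if (is.null(seed)) seed <- sub_seed(cfg$seed, paste0("track:", name))
  roi <- if (!is.null(regions_of_interest) && nrow(regions_of_interest) > 0L)
    gintervals(regions_of_interest) else NULL
  withr::with_seed(seed, {
    G <- sum(genome)
    roi_len <- if (is.null(roi)) 0 else sum(roi$end - roi$start)
    p_in <- bias * roi_len / (bias * roi_len + (G - roi_len))
    inside <- if (roi_len > 0) stats::runif(n_features) < p_in
      else rep(FALSE, n_features)
    chrom <- character(n_features)
    mpos <- numeric(n_features)
    n_in <- sum(inside)
    if (n_in > 0L) {
      # uniform position within the ROI union
      lens <- roi$end - roi$start
      pick <- sample.int(nrow(roi), n_in, replace = TRUE, prob = lens)
      chrom[inside] <- roi$chrom[pick]
      mpos[inside] <- floor(roi$start[pick] + stats::runif(n_in) * lens[pick])
    }
    n_out <- n_features - n_in
    if (n_out > 0L) {
      # uniform on the genome, rejecting ROI hits
      got <- 0L
      och <- character(n_out); opo <- numeric(n_out)
      while (got < n_out) {
        m <- (n_out - got) * 2L + 10L
        ch <- sample(names(genome), m, replace = TRUE, prob = genome)
        po <- floor(stats::runif(m) * genome[ch])
        ok <- rep(TRUE, m)
        if (!is.null(roi)) {
          for (r in seq_len(nrow(roi)))
            ok <- ok & !(ch == roi$chrom[r] & po >= roi$start[r] &
                           po < roi$end[r])
        }
        take <- min(sum(ok), n_out - got)
        sel <- which(ok)[seq_len(take)]
        och[got + seq_len(take)] <- ch[sel]
        opo[got + seq_len(take)] <- po[sel]
        got <- got + take
      }
      chrom[!inside] <- och
      mpos[!inside] <- opo
    }
    half <- floor(feature_length / 2)
    start <- pmax(0, pmin(mpos - half, genome[chrom] - feature_length))
    iv <- gintervals(chrom, start, start + feature_length,
                     sprintf("%s_%05d", name, seq_len(n_features)))
    feature_track(name, iv)
  })
}

#' Simulate a sparse Hi-C contact map
#'
#' Background entries appear with probability decaying in bin distance
#' and carry KR-normalized-style signal following a power-law decay with
#' exponential noise; `truth$hic_true_pairs` anchors get their planted
#' signal level. Absent entries mean zero.
#'
#' @param truth a [synthetic_truth()]; `hic_true_pairs` rows on `chrom`
#'   are planted.
#' @param resolution bin size in bp (> 0).
#' @param cfg a [sim_config()].
#' @param chrom chromosome to simulate (default: first in the genome).
#' @param density occupancy scale: occupancy probability at distance d
#'   bins is `min(1, density / (1 + d))`.
#' @param decay signal decay exponent; mean signal at distance d is
#'   `signal_scale / (1 + d)^decay`.
#' @param signal_scale baseline signal scale.
#' @return A [hic_map()].
#' @export
simulate_hic <- function(truth, resolution, cfg,
                         chrom = names(cfg$chrom_lengths)[1L],
                         density = 8, decay = 1, signal_scale = 2) {
  if (resolution <= 0) stop("resolution must be > 0", call. = FALSE)
  L <- cfg$chrom_lengths[[chrom]]
  n_bins <- as.integer(ceiling(L / resolution))
  withr::with_seed(sub_seed(cfg$seed, paste0("hic:", chrom)), {
    ij <- which(upper.tri(matrix(0, n_bins, n_bins), diag = TRUE),
                arr.ind = TRUE)
    d <- ij[, 2L] - ij[, 1L]
    keep <- stats::runif(nrow(ij)) < pmin(1, density / (1 + d))
    ij <- ij[keep, , drop = FALSE]
    d <- d[keep]
    sig <- signal_scale / (1 + d)^decay * stats::rexp(length(d))
    ent <- data.frame(bin1 = ij[, 1L] - 1L, bin2 = ij[, 2L] - 1L,
                      signal = sig)
    tp <- truth$hic_true_pairs
    if (!is.null(tp)) {
      tp <- tp[tp$chrom == chrom, , drop = FALSE]
      for (k in seq_len(nrow(tp))) {
        b1 <- interval_to_bins(list(start = tp$cnv_start[k],
                                    end = tp$cnv_end[k]), resolution)
        b2 <- interval_to_bins(list(start = tp$cpg_start[k],
                                    end = tp$cpg_end[k]), resolution)
        if (max(b1, b2) >= n_bins)
          stop("planted anchor lies off the chromosome", call. = FALSE)
        grid <- expand.grid(bin1 = b1, bin2 = b2)
        lo <- pmin(grid$bin1, grid$bin2)
        hi <- pmax(grid$bin1, grid$bin2)
        ent <- rbind(ent[!(paste(ent$bin1, ent$bin2) %in% paste(lo, hi)), ],
                     data.frame(bin1 = lo, bin2 = hi, signal = tp$signal[k]))
      }
    }
    hic_map(ent, resolution = resolution, chrom = chrom, n_bins = n_bins)
  })
}
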