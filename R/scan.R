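#' Scan configuration
#'
#' Settings for a genome-wide QTL scan. The proximal window is the 2 Mb
#' region centered on the phenotype's midpoint (1 Mb up- and downstream,
#' `window_half_width = 1e6`); same-chromosome variants outside it are
#' distal; different chromosomes are not tested.
#'
#' @param window_half_width half-width of the proximal window in bp.
#' @param scan_kind one of `"cnv-mqtl"`, `"cnv-eqtl"`, `"eqtm"` (label
#'   only; the engine is shared).
#' @param threshold permutation p-value cutoff for significance calls.
#' @param n_perm,seed permutation scheme settings (see
#'   [permutation_scheme()]).
#' @param min_maf optional MAF filter on variants (default: none; scans
#'   annotate MAF but keep rare variants).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(window_half_width = 1e6,
                        scan_kind = c("cnv-mqtl", "cnv-eqtl", "eqtm"),
                        threshold = 0.01, n_perm = 1000L, seed = 1L,
                        min_maf = NULL) {
  scan_kind <- match.arg(scan_kind)
  if (window_half_width <= 0) stop("window_half_width must be > 0",
                                   call. = FALSE)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)",
                                             call. = FALSE)
  structure(list(window_half_width = window_half_width,
                 scan_kind = scan_kind, threshold = threshold,
                 scheme = permutation_scheme(n_perm, seed),
                 min_maf = min_maf),
            class = "scan_config")
}

#' Classify a variant-phenotype pairing
#'
#' A variant is proximal to a phenotype site when its interval overlaps
#' the window `[midpoint - W, midpoint + W)` by at least 1 bp (variants
#' can be long, so overlap rather than a point test decides membership),
#' distal when it lies on the same chromosome wholly outside that
#' window, and untested on a different chromosome.
#'
#' @param variant,phenotype_site single-interval rows (or lists with
#'   `chrom`, `start`, `end`).
#' @param cfg a [scan_config()] (supplies the window half-width).
#' @return `"proximal"`, `"distal"`, or `"untested"`.
#' @export
classify_pairing <- function(variant, phenotype_site, cfg = scan_config()) {
  if (variant$chrom != phenotype_site$chrom) return("untested")
  mid <- floor((phenotype_site$start + phenotype_site$end) / 2)
  w <- cfg$window_half_width
  if (variant$start < mid + w && variant$end > mid - w) "proximal" else "distal"
}

#' Genome-wide QTL scan
#'
#' For every phenotype row, tests all proximal and distal candidate
#' variants by Spearman rank correlation and applies per-phenotype
#' permutation correction separately to the proximal and distal
#' families (one shuffle stream per phenotype serves both). For eQTM
#' scans the "variant" role is played by CpG methylation rows and the
#' phenotype by gene expression.
#'
#' Monomorphic variant rows and constant phenotypes are skipped and
#' counted (attribute `skipped`). Records carry the signed distance
#' (variant midpoint minus phenotype midpoint). Output ordering and the
#' per-phenotype shuffle streams are deterministic given `cfg`'s seed
#' and invariant to row order.
#'
#' @param genotypes a [genotype_matrix()] (or, for eQTM, a
#'   [methylation_matrix()]) supplying the tested "variant" rows.
#' @param phenotypes a [methylation_matrix()] or [expression_matrix()].
#' @param cfg a [scan_config()].
#' @return Data frame of association records with columns `variant_id`,
#'   `phenotype_id`, `mode`, `distance`, `rho`, `nominal_p`, `perm_p`,
#'   sorted by `(phenotype_id, mode, perm_p, variant_id)`. Attributes:
#'   `variant_universe` (all variant ids scanned), `n_phenotypes_tested`,
#'   `skipped`.
#' @export
run_scan <- function(genotypes, phenotypes, cfg = scan_config()) {
  stopifnot(inherits(cfg, "scan_config"))
  al <- align_samples(genotypes, phenotypes)
  g <- al$g; p <- al$p
  if (length(g$samples) < 3L) stop("need >= 3 shared samples", call. = FALSE)

  keep <- !apply(g$values, 1L, is_constant)
  if (!is.null(cfg$min_maf) && inherits(g, "genotype_matrix"))
    keep <- keep & genotype_maf(g) >= cfg$min_maf
  n_mono <- sum(!keep)
  gv <- g$values[keep, , drop = FALSE]
  giv <- g$intervals[keep, , drop = FALSE]
  vchrom <- giv$chrom
  vstart <- giv$start
  vend <- giv$end
  vmid <- interval_midpoint(giv)
  w <- cfg$window_half_width

  const_pheno <- apply(p$values, 1L, is_constant)
  n_const <- sum(const_pheno)
  pheno_idx <- which(!const_pheno)

  out <- vector("list", length(pheno_idx))
  for (k in seq_along(pheno_idx)) {
    i <- pheno_idx[k]
    site <- p$intervals[i, ]
    mid <- floor((site$start + site$end) / 2)
    same <- vchrom == site$chrom
    prox <- same & (vstart < mid + w) & (vend > mid - w)
    dist <- same & !prox
    cand <- which(same)
    if (length(cand) == 0L) next
    fam <- list(proximal = match(which(prox), cand),
                distal = match(which(dist), cand))
    fam <- fam[lengths(fam) > 0L]
    res <- scan_phenotype_kernel(
      p$values[i, ], gv[cand, , drop = FALSE], fam,
      n_perm = cfg$scheme$n_perm,
      seed = sub_seed(cfg$scheme$seed, site$id)
    )
    out[[k]] <- data.frame(
      variant_id = giv$id[cand],
      phenotype_id = site$id,
      mode = ifelse(prox[cand], "proximal", "distal"),
      distance = vmid[cand] - mid,
      rho = res$rho, nominal_p = res$nominal_p, perm_p = res$perm_p,
      stringsAsFactors = FALSE
    )
  }
  rec <- do.call(rbind, out)
  if (is.null(rec)) rec <- data.frame(
    variant_id = character(), phenotype_id = character(),
    mode = character(), distance = numeric(), rho = numeric(),
    nominal_p = numeric(), perm_p = numeric(), stringsAsFactors = FALSE)
  rec <- rec[order(rec$phenotype_id, rec$mode, rec$perm_p, rec$variant_id), ,
             drop = FALSE]
  rownames(rec) <- NULL
  if (n_mono + n_const > 0L)
    msg(sprintf("run_scan: skipped %d monomorphic variant row(s), %d constant phenotype(s)",
                n_mono, n_const))
  attr(rec, "variant_universe") <- sort(g$intervals$id)
  attr(rec, "n_phenotypes_tested") <- length(pheno_idx)
  attr(rec, "skipped") <- c(monomorphic = n_mono, constant_phenotype = n_const)
  rec
}

#' Summarize a scan
#'
#' Significance counts and the unsigned-distance histogram for an
#' association table.
#'
#' @param records output of [run_scan()].
#' @param threshold permutation p-value cutoff.
#' @param bin_width histogram bin width in bp for |distance|.
#' @return List of counts (`n_associations`, `n_proximal`, `n_distal`,
#'   `n_unique_variants`, `n_unique_phenotypes`, `n_both_mode_variants`)
#'   plus `distance_histogram` (data frame of bin, count).
#' @export
summarize_scan <- function(records, threshold = 0.01, bin_width = 1e6) {
  sig <- call_significant(records, threshold)
  both <- intersect(sig$variant_id[sig$mode == "proximal"],
                    sig$variant_id[sig$mode == "distal"])
  hist_df <- if (nrow(sig) > 0L) {
    bin <- floor(abs(sig$distance) / bin_width)
    tab <- table(bin)
    data.frame(bin_start = as.numeric(names(tab)) * bin_width,
               count = as.integer(tab))
  } else data.frame(bin_start = numeric(), count = integer())
  list(
    n_associations = nrow(sig),
    n_proximal = sum(sig$mode == "proximal"),
    n_distal = sum(sig$mode == "distal"),
    n_unique_variants = length(unique(sig$variant_id)),
    n_unique_phenotypes = length(unique(sig$phenotype_id)),
    n_both_mode_variants = length(both),
    distance_histogram = hist_df
  )
}

#' Cross-scan overlap of mQTL and eQTL results
#'
#' Reports CNVs significant in both a methylation scan and an expression
#' scan, and (when a CpG-to-gene map is supplied) genes whose
#' methylation and expression are associated with the same CNV.
#'
#' @param mqtl,eqtl association tables from [run_scan()] scored against
#'   the same genotype matrix (checked via their `variant_universe`
#'   attributes).
#' @param threshold permutation p-value cutoff.
#' @param cpg_gene optional data frame `(cpg_id, gene_id)` mapping
#'   methylation phenotypes to genes.
#' @return List with `shared_variants`, `genes_same_both`, and
#'   `genes_expr_assoc` (genes whose expression associates with a shared
#'   CNV).
#' @export
overlap_mqtl_eqtl <- function(mqtl, eqtl, threshold = 0.01, cpg_gene = NULL) {
  um <- attr(mqtl, "variant_universe")
  ue <- attr(eqtl, "variant_universe")
  if (!is.null(um) && !is.null(ue) && !identical(um, ue))
    stop("mQTL and eQTL scans were run against different variant universes",
         call. = FALSE)
  sm <- call_significant(mqtl, threshold)
  se <- call_significant(eqtl, threshold)
  shared <- intersect(unique(sm$variant_id), unique(se$variant_id))
  genes_expr <- sort(unique(se$phenotype_id[se$variant_id %in% shared]))
  genes_same <- character()
  if (!is.null(cpg_gene) && length(shared) > 0L) {
    mg <- merge(sm[sm$variant_id %in% shared, c("variant_id", "phenotype_id")],
                cpg_gene, by.x = "phenotype_id", by.y = "cpg_id")
    eg <- se[se$variant_id %in% shared, c("variant_id", "phenotype_id")]
    names(eg)[2L] <- "gene_id"
    genes_same <- sort(unique(merge(mg[, c("variant_id", "gene_id")], eg)$gene_id))
  }
  list(shared_variants = sort(shared),
       genes_same_both = genes_same,
       genes_expr_assoc = genes_expr)
}

#' Replicate discovery associations in a validation cohort
#'
#' Re-runs the association engine in a second cohort restricted to the
#' variant-phenotype pairs called significant in a discovery scan, and
#' reports the replication fraction at permutation p < 0.01 and
#' p < 0.05.
#'
#' @param discovery association table from a discovery [run_scan()].
#' @param genotypes,phenotypes validation-cohort matrices.
#' @param cfg a [scan_config()] for the validation run.
#' @param discovery_threshold cutoff defining the discovery-significant
#'   set to carry forward.
#' @return List with the validation `records` (restricted pairs),
#'   `n_tested`, `n_replicated_p01`, `n_replicated_p05`, and the two
#'   replication fractions.
#' @export
replicate_scan <- function(discovery, genotypes, phenotypes,
                           cfg = scan_config(), discovery_threshold = 0.01) {
  sig <- call_significant(discovery, discovery_threshold)
  if (nrow(sig) == 0L) stop("no discovery-significant pairs to replicate",
                            call. = FALSE)
  rec <- run_scan(genotypes, phenotypes, cfg)
  key <- paste(rec$variant_id, rec$phenotype_id)
  rec <- rec[key %in% paste(sig$variant_id, sig$phenotype_id), , drop = FALSE]
  list(records = rec,
       n_tested = nrow(rec),
       n_replicated_p01 = sum(rec$perm_p < 0.01),
       n_replicated_p05 = sum(rec$perm_p < 0.05),
       frac_p01 = if (nrow(rec)) sum(rec$perm_p < 0.01) / nrow(rec) else NA_real_,
       frac_p05 = if (nrow(rec)) sum(rec$perm_p < 0.05) / nrow(rec) else NA_real_)
}
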