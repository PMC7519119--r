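#' Sparse binned Hi-C contact map
#'
#' Holds KR-normalized contact signal for one chromosome at one
#' resolution as a sparse symmetric matrix; entries are stored with
#' `bin1 <= bin2`, absent entries mean zero, and access is symmetric.
#'
#' @param entries data frame with columns `bin1`, `bin2` (0-based bin
#'   indices) and `signal` (>= 0).
#' @param resolution bin size in bp.
#' @param chrom chromosome name.
#' @param n_bins number of bins on the chromosome.
#' @return An object of class `hic_map`.
#' @export
hic_map <- function(entries, resolution, chrom, n_bins) {
  stopifnot(all(c("bin1", "bin2", "signal") %in% names(entries)))
  if (any(entries$signal < 0)) stop("signals must be >= 0", call. = FALSE)
  lo <- pmin(entries$bin1, entries$bin2)
  hi <- pmax(entries$bin1, entries$bin2)
  if (any(hi >= n_bins) || any(lo < 0))
    stop("bin index outside the chromosome", call. = FALSE)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    agg <- tapply(entries$signal, key, max)
    parts <- do.call(rbind, strsplit(names(agg), " "))
    lo <- as.integer(parts[, 1L]); hi <- as.integer(parts[, 2L])
    sig <- as.numeric(agg)
  } else sig <- entries$signal
  m <- Matrix::sparseMatrix(i = lo + 1L, j = hi + 1L, x = sig,
                            dims = c(n_bins, n_bins), symmetric = TRUE)
  structure(list(resolution = resolution, chrom = chrom, n_bins = n_bins,
                 matrix = m,
                 entries = data.frame(bin1 = lo, bin2 = hi, signal = sig)),
            class = "hic_map")
}

#' @export
print.hic_map <- function(x, ...) {
  cat(sprintf("<hic_map> %s @ %d bp: %d bins, %d non-zero entries\n",
              x$chrom, as.integer(x$resolution), x$n_bins,
              nrow(x$entries)))
  invisible(x)
}

#' Read a binned contact TSV
#'
#' Three tab-separated columns: `bin1_start`, `bin2_start` (bp, bin
#' left edges) and the KR-normalized signal.
#'
#' @param path file path.
#' @param resolution bin size in bp.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp (sets the bin count).
#' @return A [hic_map()].
#' @export
read_contacts <- function(path, resolution, chrom, chrom_length) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  stopifnot(ncol(df) >= 3L)
  hic_map(data.frame(bin1 = df[[1L]] %/% resolution,
                     bin2 = df[[2L]] %/% resolution,
                     signal = df[[3L]]),
          resolution = resolution, chrom = chrom,
          n_bins = as.integer(ceiling(chrom_length / resolution)))
}

#' @rdname read_contacts
#' @param map a [hic_map()].
#' @export
write_contacts <- function(map, path) {
  df <- data.frame(bin1_start = map$entries$bin1 * map$resolution,
                   bin2_start = map$entries$bin2 * map$resolution,
                   signal = map$entries$signal)
  df <- df[order(df$bin1_start, df$bin2_start), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map an interval to bin indices
#'
#' Bins are `floor(start / resolution) .. floor((end - 1) / resolution)`
#' inclusive (half-open interval arithmetic).
#'
#' @param iv a list or single-row interval with `start`, `end`.
#' @param resolution bin size in bp (> 0).
#' @return Integer vector of 0-based bin indices.
#' @export
interval_to_bins <- function(iv, resolution) {
  if (resolution <= 0) stop("resolution must be > 0", call. = FALSE)
  if (iv$end <= iv$start) stop("empty interval", call. = FALSE)
  seq.int(iv$start %/% resolution, (iv$end - 1) %/% resolution)
}

#' Contact signal for a CNV-CpG pair
#'
#' Extends the CpG region by `window_bp` on both sides (to include
#' shores), maps both regions to bins, and returns the maximum
#' KR-normalized signal over all (CNV bin, CpG bin) combinations; the
#' pair is `nonzero` when that maximum is positive.
#'
#' @param cnv,cpg single-row intervals on the map's chromosome.
#' @param window_bp CpG extension in bp (2,000 or 5,000 in the
#'   genome-scale analysis).
#' @param map a [hic_map()].
#' @return List `(signal, nonzero, cnv_bins, cpg_bins)`.
#' @export
pair_signal <- function(cnv, cpg, window_bp, map) {
  stopifnot(inherits(map, "hic_map"))
  if (!is.null(cnv$chrom) && !is.null(cpg$chrom) &&
      cnv$chrom != cpg$chrom)
    stop("inter-chromosomal pair: contacts are intra-chromosomal only",
         call. = FALSE)
  lim <- map$n_bins * map$resolution
  ext <- list(start = max(0, cpg$start - window_bp),
              end = min(lim, cpg$end + window_bp))
  b1 <- interval_to_bins(cnv, map$resolution)
  b2 <- interval_to_bins(ext, map$resolution)
  b1 <- b1[b1 < map$n_bins]
  b2 <- b2[b2 < map$n_bins]
  if (length(b1) == 0L || length(b2) == 0L)
    stop("pair lies outside the contact map", call. = FALSE)
  sub <- map$matrix[b1 + 1L, b2 + 1L, drop = FALSE]
  sig <- max(0, max(sub))
  list(signal = sig, nonzero = sig > 0, cnv_bins = b1, cpg_bins = b2)
}

#' Sample size- and distance-matched random pairs
#'
#' Builds a random pair set mirroring an observed CNV-CpG pair list,
#' per chromosome: region lengths for both roles are permutations of
#' the observed length multisets, pair distances (midpoint to midpoint)
#' are a permutation of the observed distance multiset, the CNV-like
#' anchor is placed uniformly, and the partner is placed at the matched
#' distance in a random direction (placements that would fall off the
#' chromosome are resampled).
#'
#' @param pairs data frame with columns `chrom`, `cnv_start`,
#'   `cnv_end`, `cpg_start`, `cpg_end` (CpG coordinates already
#'   shore-extended if desired).
#' @param genome named vector of chromosome lengths.
#' @param seed integer seed.
#' @return Data frame shaped like `pairs`.
#' @export
sample_matched_pairs <- function(pairs, genome, seed) {
  need <- c("chrom", "cnv_start", "cnv_end", "cpg_start", "cpg_end")
  stopifnot(all(need %in% names(pairs)))
  withr::with_seed(seed, {
    out <- pairs
    for (ch in unique(pairs$chrom)) {
      idx <- which(pairs$chrom == ch)
      L <- genome[[ch]]
      cnv_len <- (pairs$cnv_end - pairs$cnv_start)[idx]
      cpg_len <- (pairs$cpg_end - pairs$cpg_start)[idx]
      dist <- abs(floor((pairs$cnv_start + pairs$cnv_end)[idx] / 2) -
                    floor((pairs$cpg_start + pairs$cpg_end)[idx] / 2))
      if (any(dist + cnv_len / 2 + cpg_len / 2 > L))
        stop("matched distance exceeds the chromosome length", call. = FALSE)
      k <- length(idx)
      cnv_len <- cnv_len[sample.int(k)]
      cpg_len <- cpg_len[sample.int(k)]
      dist <- dist[sample.int(k)]
      cnv_start <- cpg_start <- numeric(k)
      for (j in seq_len(k)) {
        repeat {
          a_start <- floor(stats::runif(1) * (L - cnv_len[j] + 1))
          a_mid <- floor(a_start + cnv_len[j] / 2)
          dirn <- sample(c(-1, 1), 1L)
          b_mid <- a_mid + dirn * dist[j]
          b_start <- b_mid - floor(cpg_len[j] / 2)
          if (b_start >= 0 && b_start + cpg_len[j] <= L) break
        }
        cnv_start[j] <- a_start
        cpg_start[j] <- b_start
      }
      out$cnv_start[idx] <- cnv_start
      out$cnv_end[idx] <- cnv_start + cnv_len
      out$cpg_start[idx] <- cpg_start
      out$cpg_end[idx] <- cpg_start + cpg_len
    }
    out
  })
}

#' Distance-matched permutation test for Hi-C contact enrichment
#'
#' Extends each observed pair's CpG by `window_bp`, counts the pairs
#' with non-zero KR-normalized signal, and compares that count against
#' `iterations` size- and distance-matched random pair sets (see
#' [sample_matched_pairs()]). `p_enrich` is the add-one upper tail; the
#' per-iteration log ratios `log((observed + 1) / (null + 1))`
#' (add-one smoothed so zero null counts stay finite) summarize the
#' enrichment magnitude.
#'
#' @param pairs data frame `(chrom, cnv_start, cnv_end, cpg_start,
#'   cpg_end)` of observed CNV-CpG pairs (non-empty).
#' @param map a [hic_map()].
#' @param window_bp CpG shore extension in bp.
#' @param iterations number of permutations (>= 100).
#' @param seed integer seed.
#' @return List `(observed, null_counts, p_enrich, log_ratios)`.
#' @export
hic_permutation_test <- function(pairs, map, window_bp = 5000L,
                                 iterations = 1000L, seed = 1L) {
  if (nrow(pairs) == 0L) stop("empty pair set", call. = FALSE)
  if (iterations < 100L) stop("iterations must be >= 100", call. = FALSE)
  genome <- stats::setNames(map$n_bins * map$resolution, map$chrom)
  ext <- pairs
  ext$cpg_start <- pmax(0, pairs$cpg_start - window_bp)
  ext$cpg_end <- pmin(genome[[map$chrom]], pairs$cpg_end + window_bp)
  nonzero_count <- function(ps) {
    sum(vapply(seq_len(nrow(ps)), function(j) {
      pair_signal(list(chrom = ps$chrom[j], start = ps$cnv_start[j],
                       end = ps$cnv_end[j]),
                  list(chrom = ps$chrom[j], start = ps$cpg_start[j],
                       end = ps$cpg_end[j]),
                  window_bp = 0L, map = map)$nonzero
    }, NA))
  }
  observed <- nonzero_count(ext)
  null_counts <- vapply(seq_len(iterations), function(it) {
    nonzero_count(sample_matched_pairs(ext, genome,
                                       seed = sub_seed(seed, paste0("it", it))))
  }, 0L)
  p_enrich <- (1 + sum(null_counts >= observed)) / (iterations + 1)
  list(observed = observed, null_counts = null_counts,
       p_enrich = p_enrich,
       log_ratios = log((observed + 1) / (null_counts + 1)))
}
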