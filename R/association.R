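#' Spearman rank correlation with asymptotic p-value
#'
#' The scan's elementary statistic: Pearson correlation of average-tie
#' ranks, with a two-sided p-value from the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom. Pairs with a missing value in either vector are dropped
#' (pairwise-complete).
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs
#'   and neither vector constant after filtering.
#' @return List with `rho`, `nominal_p`, and `n` (complete pairs used).
#' @examples
#' rank_correlation(c(0, 1, 2, 3), c(0.1, 0.2, 0.3, 0.4))$rho  # 1
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  zx <- zrank(x)
  zy <- zrank(y)
  rho <- sum(zx * zy) / (n - 1)
  rho <- max(-1, min(1, rho))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, nominal_p = p, n = n)
}

#' Permutation scheme for multiple-test correction
#'
#' Describes the per-phenotype permutation family: the phenotype vector
#' is shuffled across samples `n_perm` times and, for each shuffle, the
#' maximum |rho| over the phenotype's tested variant set is recorded.
#' Each tested pair's permutation p-value is the add-one empirical tail
#' `(1 + #\{max-null >= |rho_obs|\}) / (n_perm + 1)`, so p-values are
#' never zero and the floor is `1 / (n_perm + 1)`.
#'
#' @param n_perm number of permutations (>= 100). Genome-scale runs use
#'   10,000; desk-scale tests default to 1,000.
#' @param seed integer seed for the shuffle stream.
#' @return An object of class `permutation_scheme`.
#' @export
permutation_scheme <- function(n_perm = 1000L, seed = 1L) {
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 100L)
    stop("n_perm must be >= 100", call. = FALSE)
  structure(list(n_perm = n_perm, seed = as.integer(seed),
                 family = "per-phenotype", estimator = "add-one"),
            class = "permutation_scheme")
}

# Shared permutation kernel. y: phenotype vector (no NA); G: variants x
# samples genotype matrix (NA allowed, handled pairwise-complete);
# families: named list of integer row-index vectors, each corrected as
# its own max-|rho| family; one shuffle stream serves all families.
# Returns per-variant rho, nominal p, and per-family perm p.
scan_phenotype_kernel <- function(y, G, families, n_perm, seed) {
  if (anyNA(y)) stop("phenotype vector contains missing values", call. = FALSE)
  if (is_constant(y)) stop("constant phenotype", call. = FALSE)
  n <- length(y)
  stopifnot(ncol(G) == n)
  nv <- nrow(G)
  zy <- zrank(y)

  obs <- vapply(seq_len(nv), function(i) {
    rank_correlation(G[i, ], y)$rho
  }, 0)
  nominal <- vapply(seq_len(nv), function(i) {
    rank_correlation(G[i, ], y)$nominal_p
  }, 0)

  perm_idx <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  })  # n x n_perm

  cc <- !apply(is.na(G), 1L, any)
  null_abs <- matrix(NA_real_, n_perm, nv)
  if (any(cc)) {
    Z <- t(apply(G[cc, , drop = FALSE], 1L, zrank))   # k x n
    if (sum(cc) == 1L) Z <- matrix(Z, nrow = 1L)
    ZYp <- matrix(zy[perm_idx], nrow = n)             # n x n_perm (zrank is
    # permutation-equivariant: ranks of y[perm] = rank(y)[perm])
    null_abs[, cc] <- abs(t(Z %*% ZYp) / (n - 1))
  }
  for (i in which(!cc)) {
    m <- !is.na(G[i, ])
    zg <- zrank(G[i, m])
    sub <- matrix(y[perm_idx], nrow = n)[m, , drop = FALSE]
    null_abs[, i] <- abs(apply(sub, 2L, function(v) {
      sum(zrank(v) * zg) / (sum(m) - 1)
    }))
  }

  perm_p <- rep(NA_real_, nv)
  for (fam in families) {
    if (length(fam) == 0L) next
    fam_max <- apply(null_abs[, fam, drop = FALSE], 1L, max)
    perm_p[fam] <- vapply(fam, function(i) {
      (1 + sum(fam_max >= abs(obs[i]))) / (n_perm + 1)
    }, 0)
  }
  list(rho = obs, nominal_p = nominal, perm_p = perm_p)
}

#' Permutation multiple-test correction for one phenotype
#'
#' Shuffles the phenotype across samples and corrects every tested
#' variant against the maximum-|rho| permutation null of the whole
#' tested set (the per-phenotype family convention of QTL mapping).
#'
#' @param phenotype numeric phenotype vector (no missing values, not
#'   constant).
#' @param genotypes numeric matrix of tested variants x samples (rows
#'   named by variant id); missing genotypes handled pairwise-complete.
#' @param scheme a [permutation_scheme()].
#' @return Data frame with one row per tested variant: `variant_id`,
#'   `rho`, `nominal_p`, `perm_p`.
#' @export
permutation_correct <- function(phenotype, genotypes, scheme = permutation_scheme()) {
  stopifnot(inherits(scheme, "permutation_scheme"))
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) == 0L) stop("empty genotype set", call. = FALSE)
  res <- scan_phenotype_kernel(phenotype, genotypes,
                               families = list(seq_len(nrow(genotypes))),
                               n_perm = scheme$n_perm, seed = scheme$seed)
  data.frame(
    variant_id = rownames(genotypes) %||% as.character(seq_len(nrow(genotypes))),
    rho = res$rho, nominal_p = res$nominal_p, perm_p = res$perm_p,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation false-discovery-rate estimate
#'
#' The scan-level FDR used with per-phenotype permutation correction:
#' `min(1, n_phenotypes_tested * cutoff / n_significant_phenotypes)` --
#' the expected number of phenotypes passing the permutation cutoff by
#' chance, divided by the number observed to pass.
#'
#' @param n_phenotypes_tested number of phenotypes scanned (> 0).
#' @param cutoff permutation p-value cutoff in (0, 1).
#' @param n_significant_phenotypes number of phenotypes called
#'   significant (> 0).
#' @return FDR fraction in (0, 1\].
#' @examples
#' estimate_fdr(100, 0.01, 100)  # 0.01
#' @export
estimate_fdr <- function(n_phenotypes_tested, cutoff, n_significant_phenotypes) {
  if (n_phenotypes_tested <= 0) stop("n_phenotypes_tested must be > 0",
                                     call. = FALSE)
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)",
                                       call. = FALSE)
  if (n_significant_phenotypes <= 0)
    stop("FDR undefined with zero significant phenotypes", call. = FALSE)
  min(1, n_phenotypes_tested * cutoff / n_significant_phenotypes)
}

#' Call significant associations
#'
#' Retains records whose permutation p-value falls strictly below the
#' cutoff, reporting per-mode counts as attributes.
#'
#' @param records association record data frame (must carry `perm_p`).
#' @param threshold permutation p-value cutoff (default 0.01, the scan's
#'   genome-wide convention).
#' @return The significant subset, with attribute `mode_counts`.
#' @export
call_significant <- function(records, threshold = 0.01) {
  stopifnot("perm_p" %in% names(records))
  sig <- records[records$perm_p < threshold, , drop = FALSE]
  counts <- if ("mode" %in% names(sig)) table(factor(sig$mode,
    levels = c("proximal", "distal"))) else table(character())
  attr(sig, "mode_counts") <- as.integer(counts)
  names(attr(sig, "mode_counts")) <- names(counts)
  sig
}
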