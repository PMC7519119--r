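#' Genotype, methylation, and expression matrices
#'
#' The three phenotype/genotype containers share one layout: an interval
#' table describing the rows (variants, CpG sites, genes), an ordered
#' sample-id vector, and a numeric matrix of row x sample values.
#'
#' * `genotype_matrix()` holds integer copy-number states (CNVs, typically
#'   0-4 around the diploid state 2) or allele dosages (SNPs, 0/1/2).
#'   Missing genotypes are allowed (`NA`) and handled pairwise-complete
#'   downstream.
#' * `methylation_matrix()` holds beta-values, methylation fractions in
#'   \[0, 1\]; missing values are rejected.
#' * `expression_matrix()` holds non-negative expression estimates;
#'   missing values are rejected.
#'
#' @param intervals interval table (see [gintervals()]) describing rows.
#' @param samples character vector of sample ids, ordered as the matrix
#'   columns.
#' @param values numeric matrix, `nrow(intervals)` x `length(samples)`.
#' @return An object of class `genotype_matrix`, `methylation_matrix`, or
#'   `expression_matrix`; a list with elements `intervals`, `samples`,
#'   and `values`.
#' @export
genotype_matrix <- function(intervals, samples, values) {
  m <- new_assay_matrix(intervals, samples, values, "genotype_matrix")
  v <- m$values[!is.na(m$values)]
  if (any(v < 0) || any(v != floor(v)))
    stop("genotype values must be non-negative integers", call. = FALSE)
  m
}

#' @rdname genotype_matrix
#' @export
methylation_matrix <- function(intervals, samples, values) {
  if (anyNA(values))
    stop("methylation matrix may not contain missing beta-values",
         call. = FALSE)
  if (any(values < 0) || any(values > 1))
    stop("beta-values must lie in [0, 1]", call. = FALSE)
  new_assay_matrix(intervals, samples, values, "methylation_matrix")
}

#' @rdname genotype_matrix
#' @export
expression_matrix <- function(intervals, samples, values) {
  if (anyNA(values))
    stop("expression matrix may not contain missing values", call. = FALSE)
  if (any(values < 0))
    stop("expression values must be non-negative", call. = FALSE)
  new_assay_matrix(intervals, samples, values, "expression_matrix")
}

new_assay_matrix <- function(intervals, samples, values, class) {
  intervals <- gintervals(intervals)
  samples <- as.character(samples)
  values <- as.matrix(values)
  if (nrow(values) != nrow(intervals))
    stop("value rows must match interval count", call. = FALSE)
  if (ncol(values) != length(samples))
    stop("value columns must match sample count", call. = FALSE)
  if (anyDuplicated(samples))
    stop("sample ids must be unique", call. = FALSE)
  dimnames(values) <- list(intervals$id, samples)
  structure(list(intervals = intervals, samples = samples, values = values),
            class = c(class, "assay_matrix"))
}

#' @export
print.assay_matrix <- function(x, ...) {
  cat(sprintf("<%s> %d rows x %d samples\n", class(x)[1L],
              nrow(x$values), length(x$samples)))
  invisible(x)
}

#' Minor allele frequency per variant
#'
#' For SNP dosages (0/1/2) this is the folded allele frequency. For
#' copy-number states the non-reference allele dosage is taken as
#' `|state - 2|` (distance from the diploid state), an order-preserving
#' coding; rank-based association downstream is invariant to any monotone
#' recoding of the genotype.
#'
#' @param g a [genotype_matrix()].
#' @return Numeric vector of per-variant MAF in \[0, 0.5\], named by
#'   variant id.
#' @export
genotype_maf <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  f <- rowMeans(abs(g$values - 2), na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Align two matrices on shared samples
#'
#' Subsets both matrices to the intersection of their sample ids, in the
#' order of the first (genotype) matrix; unmatched samples are dropped
#' with a warning.
#'
#' @param g,p two assay matrices.
#' @return List with the two aligned matrices, `g` and `p`.
#' @export
align_samples <- function(g, p) {
  shared <- g$samples[g$samples %in% p$samples]
  if (length(shared) == 0L)
    stop("no shared samples between matrices", call. = FALSE)
  dropped <- length(unique(c(g$samples, p$samples))) - length(shared)
  if (dropped > 0L)
    warning(sprintf("dropping %d unmatched sample(s) during alignment",
                    dropped), call. = FALSE)
  g$values <- g$values[, shared, drop = FALSE]
  g$samples <- shared
  p$values <- p$values[, shared, drop = FALSE]
  p$samples <- shared
  list(g = g, p = p)
}
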