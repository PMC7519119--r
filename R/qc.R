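#' Quantile-normalize a methylation matrix
#'
#' Replaces each sample column's beta-values by the rank-wise mean of the
#' sorted columns (delegating to [limma::normalizeQuantiles()]), so all
#' samples share one value distribution while each sample's rank order is
#' preserved. Applied to validation-cohort beta-values before
#' re-association, mirroring array-harmonization practice.
#'
#' @param m a [methylation_matrix()] with at least 2 samples and no
#'   missing values.
#' @return A quantile-normalized [methylation_matrix()].
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "methylation_matrix"))
  if (length(m$samples) < 2L)
    stop("quantile normalization needs >= 2 samples", call. = FALSE)
  norm <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(norm) <- dimnames(m$values)
  m$values <- norm
  m
}

#' Principal-component stratification check
#'
#' PCA of a samples x features matrix (internally centered), used to
#' check a cohort for population stratification before association:
#' well-separated sample clusters on the leading components indicate
#' structure that would confound the scan.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param k number of components to return; must be smaller than
#'   `min(nrow(x), ncol(x))`.
#' @return List with `scores` (samples x k), `explained` (fraction of
#'   variance per returned component, non-increasing). Component signs
#'   are canonicalized (largest-magnitude loading positive) so results
#'   are deterministic.
#' @export
pca_qc <- function(x, k = 2L) {
  x <- as.matrix(x)
  if (k >= min(dim(x)))
    stop("k must be < min(n_samples, n_features)", call. = FALSE)
  ctr <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(ctr) < .Machine$double.eps * 100))
    stop("constant matrix: no variance to decompose", call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(k), function(j) {
    l <- p$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0)
  scores <- sweep(p$x[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  expl <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k)]
  list(scores = scores, explained = expl)
}
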