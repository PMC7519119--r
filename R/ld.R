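#' Linkage disequilibrium between two genotype vectors
#'
#' Squared Pearson correlation of the raw genotype vectors,
#' pairwise-complete; the LD measure used to ask whether a CNV is tagged
#' by nearby SNPs.
#'
#' @param a,b numeric genotype vectors of equal length; >= 3 complete
#'   pairs, neither constant.
#' @return r-squared in \[0, 1\].
#' @examples
#' ld_r2(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 0
#' @export
ld_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length", call. = FALSE)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (is_constant(a) || is_constant(b))
    stop("constant vector: LD undefined", call. = FALSE)
  stats::cor(a, b)^2
}

#' Best tagging SNP for a CNV
#'
#' Among SNPs whose position lies within `window` bp of the CNV interval
#' (closest gap between the SNP start and the interval's ends), returns
#' the record with the largest r-squared; ties break to the
#' lower-coordinate SNP. Returns `NULL` when no SNP qualifies.
#'
#' @param cnv single-row interval (the CNV) paired with its genotype
#'   vector `cnv_geno`.
#' @param cnv_geno numeric genotype vector for the CNV.
#' @param snps a [genotype_matrix()] of coordinate-annotated SNPs.
#' @param window search window in bp (default 1 Mb).
#' @return List `(cnv_id, snp_id, r2, distance)` or `NULL`.
#' @export
best_tag_snp <- function(cnv, cnv_geno, snps, window = 1e6) {
  pos <- snps$intervals$start
  gap <- ifelse(pos < cnv$start, cnv$start - pos,
                ifelse(pos >= cnv$end, pos - (cnv$end - 1), 0))
  cand <- which(snps$intervals$chrom == cnv$chrom & gap <= window)
  if (length(cand) == 0L) return(NULL)
  r2 <- vapply(cand, function(i) {
    g <- snps$values[i, ]
    if (is_constant(g) || is_constant(cnv_geno)) return(NA_real_)
    ld_r2(cnv_geno, g)
  }, 0)
  if (all(is.na(r2))) return(NULL)
  ord <- order(-r2, pos[cand])
  best <- cand[ord[1L]]
  list(cnv_id = cnv$id, snp_id = snps$intervals$id[best],
       r2 = r2[ord[1L]], distance = gap[best])
}

#' Conditional CNV association given SNP covariates
#'
#' Re-tests a CNV-CpG association with nearby SNP-mQTL genotypes as
#' covariates: ordinary least squares of the rank-transformed phenotype
#' on the SNP covariates plus the CNV term (rank transform keeps the
#' spirit of the Spearman scan), with a two-sided t-test on the CNV
#' coefficient. The CNV effect is called independent when its
#' conditional p falls below 0.05. With no covariates the test reduces
#' to the marginal linear-model test. A covariate collinear with the CNV
#' (r-squared 1) makes the CNV term non-identifiable; the result is
#' flagged and `independent` is `FALSE`.
#'
#' @param cpg_beta numeric phenotype vector.
#' @param cnv numeric CNV genotype vector.
#' @param snp_covariates numeric matrix of covariate SNP genotypes
#'   (samples in columns, one row per SNP), or `NULL`.
#' @param max_covariates cap on the number of covariates entered
#'   (strongest r-squared with the CNV first).
#' @param alpha independence threshold on the conditional p.
#' @return List `(conditional_p, independent, identifiable,
#'   n_covariates)`.
#' @export
conditional_association <- function(cpg_beta, cnv, snp_covariates = NULL,
                                    max_covariates = 10L, alpha = 0.05) {
  y <- rank(cpg_beta, ties.method = "average")
  n <- length(y)
  X <- if (is.null(snp_covariates)) NULL else {
    m <- as.matrix(snp_covariates)
    if (ncol(m) == n && nrow(m) != n) t(m) else m  # samples in rows
  }
  if (!is.null(X) && ncol(X) > 0L) {
    keep <- !apply(X, 2L, is_constant)
    X <- X[, keep, drop = FALSE]
    if (ncol(X) > max_covariates) {
      r2c <- apply(X, 2L, function(s) stats::cor(cnv, s)^2)
      X <- X[, order(-r2c)[seq_len(max_covariates)], drop = FALSE]
    }
  }
  k <- if (is.null(X)) 0L else ncol(X)
  if (n < 2L + k + 1L) stop("too few samples for the conditional model",
                            call. = FALSE)
  if (k > 0L) {
    collinear <- apply(X, 2L, function(s) {
      !is_constant(s) && !is_constant(cnv) && ld_r2(cnv, s) >= 1 - 1e-12
    })
    if (any(collinear))
      return(list(conditional_p = NA_real_, independent = FALSE,
                  identifiable = FALSE, n_covariates = k))
    df <- data.frame(y = y, cnv = cnv, X)
    fit <- stats::lm(y ~ ., data = df)
  } else {
    fit <- stats::lm(y ~ cnv)
  }
  cf <- summary(fit)$coefficients
  if (!("cnv" %in% rownames(cf)) || is.na(coef(fit)["cnv"]))
    return(list(conditional_p = NA_real_, independent = FALSE,
                identifiable = FALSE, n_covariates = k))
  p <- cf["cnv", "Pr(>|t|)"]
  list(conditional_p = p, independent = p < alpha, identifiable = TRUE,
       n_covariates = k)
}
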