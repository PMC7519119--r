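#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd rnorm runif rbinom rexp pt approx prcomp lm
#'   quantile complete.cases setNames plogis median coef
#' @importFrom utils write.table head
NULL

# Stable sub-seed derivation: one global seed fans out into independent,
# reproducible streams keyed by a short tag (generator name, phenotype id).
# Kept below 2^31 - 1 so it is always a valid R integer seed.
sub_seed <- function(seed, tag) {
  codes <- utf8ToInt(as.character(tag))
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((as.numeric(seed) %% 2147483647 + 10007 * h) %% 2147483647)
}

# Standardized average ranks: Pearson correlation of these vectors is the
# Spearman rank correlation with tie correction.
zrank <- function(x) {
  r <- rank(x, ties.method = "average")
  s <- stats::sd(r)
  if (s == 0) stop("constant vector: rank correlation undefined", call. = FALSE)
  (r - mean(r)) / s
}

is_constant <- function(x) {
  x <- x[!is.na(x)]
  length(x) < 1L || all(x == x[1L])
}

msg <- function(..., quiet = getOption("cnvmqtl.quiet", FALSE)) {
  if (!isTRUE(quiet)) message(...)
}
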