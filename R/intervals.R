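#' Genomic interval tables
#'
#' Interval sets are plain data frames with columns `chrom`, `start`,
#' `end`, `id`, using 0-based half-open (BED) coordinates. `gintervals()`
#' validates and normalizes such a table; `interval_midpoint()` returns
#' the integer midpoint `floor((start + end) / 2)` used to anchor
#' proximal/distal windows.
#'
#' @param chrom character chromosome names, or a data frame already
#'   holding the four columns.
#' @param start,end integer positions, 0-based half-open (`end`
#'   exclusive, `end > start`).
#' @param id stable identifiers, unique within the set; auto-generated as
#'   `"chrom:start-end"` when missing.
#' @return A data frame with columns `chrom`, `start`, `end`, `id`.
#' @examples
#' gintervals("chr1", 100, 200, "A")
#' @export
gintervals <- function(chrom, start = NULL, end = NULL, id = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
    if (is.null(df$id)) df$id <- NULL
    return(gintervals(df$chrom, df$start, df$end, df$id))
  }
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(start)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n)
    stop("chrom/start/end lengths differ", call. = FALSE)
  if (any(is.na(start)) || any(is.na(end)) || any(start != floor(start)) ||
      any(end != floor(end)))
    stop("interval coordinates must be integers", call. = FALSE)
  if (any(start < 0)) stop("interval start must be >= 0", call. = FALSE)
  if (any(end <= start)) stop("interval end must exceed start", call. = FALSE)
  if (is.null(id)) id <- sprintf("%s:%d-%d", chrom, start, end)
  id <- as.character(id)
  if (anyDuplicated(id)) stop("interval ids must be unique", call. = FALSE)
  data.frame(chrom = chrom, start = start, end = end, id = id,
             stringsAsFactors = FALSE)
}

#' @rdname gintervals
#' @param x an interval table.
#' @export
interval_midpoint <- function(x) {
  floor((x$start + x$end) / 2)
}

# GRanges view of an interval table (1-based closed, as IRanges expects).
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    id = x$id
  )
}

#' Feature tracks
#'
#' A feature track is a named set of genomic intervals (a regulatory-mark
#' peak set, CpG islands, a VMR/T-DMR catalog, ...).
#'
#' @param name non-empty track label.
#' @param intervals interval table (see [gintervals()]).
#' @return An object of class `feature_track`.
#' @export
feature_track <- function(name, intervals) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("track name must be a non-empty string", call. = FALSE)
  intervals <- gintervals(intervals)
  structure(list(name = name, intervals = intervals),
            class = "feature_track")
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("<feature_track> %s: %d intervals on %d chromosome(s)\n",
              x$name, nrow(x$intervals), length(unique(x$intervals$chrom))))
  invisible(x)
}

track_intervals <- function(track) {
  if (inherits(track, "feature_track")) track$intervals else gintervals(track)
}
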