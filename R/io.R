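#' Read a BED (3-4 column) interval file
#'
#' Parses whitespace/tab-delimited BED with 0-based half-open
#' coordinates. A fourth column, when present, supplies interval ids;
#' otherwise ids are auto-generated as `"chrom:start-end"`. Malformed
#' lines (non-integer coordinates, `end <= start`, fewer than 3 fields)
#' raise an error naming the line number.
#'
#' @param path file path.
#' @param name track label; defaults to the file's base name.
#' @return A [feature_track()].
#' @export
read_bed <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.bed$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("no data lines in BED file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("BED parse error at line %d: fewer than 3 fields",
                 idx[which(nf < 3L)[1L]]), call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad))
    stop(sprintf("BED parse error at line %d: non-integer coordinates",
                 idx[which(bad)[1L]]), call. = FALSE)
  bad <- end <= start | start < 0
  if (any(bad))
    stop(sprintf("BED parse error at line %d: end must exceed start >= 0",
                 idx[which(bad)[1L]]), call. = FALSE)
  id <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
               sprintf("%s:%d-%d", chrom, start, end))
  feature_track(name, gintervals(chrom, start, end, id))
}

#' Write a feature track as BED
#'
#' Canonical 4-column tab-separated output; `read_bed(write_bed(x))`
#' round-trips byte-identically for canonical input.
#'
#' @param track a [feature_track()] or interval table.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(track, path) {
  iv <- track_intervals(track)
  writeLines(sprintf("%s\t%d\t%d\t%s", iv$chrom, iv$start, iv$end, iv$id),
             path)
  invisible(path)
}

#' Read a coordinate-annotated matrix TSV
#'
#' Expected dialect: a header line, first four columns `chrom`, `start`,
#' `end`, `id`, remaining columns one per sample. `"NA"` cells are
#' tolerated only for `kind = "genotype"` (they enter the missing mask);
#' methylation and expression matrices reject them, and beta-values
#' outside \[0, 1\] or duplicate row ids are errors.
#'
#' @param path file path.
#' @param kind `"genotype"`, `"methylation"`, or `"expression"`.
#' @return The corresponding assay matrix (see [genotype_matrix()]).
#' @export
read_matrix <- function(path, kind = c("genotype", "methylation", "expression")) {
  kind <- match.arg(kind)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE)
  need <- c("chrom", "start", "end", "id")
  if (!all(need %in% names(dt)[seq_len(4L)]))
    stop("matrix TSV must start with columns chrom/start/end/id",
         call. = FALSE)
  iv <- gintervals(dt$chrom, dt$start, dt$end, dt$id)
  samples <- names(dt)[-seq_len(4L)]
  if (length(samples) == 0L) stop("matrix TSV has no sample columns",
                                  call. = FALSE)
  vals <- as.matrix(dt[, -seq_len(4L), drop = FALSE])
  storage.mode(vals) <- "double"
  switch(kind,
    genotype = genotype_matrix(iv, samples, vals),
    methylation = methylation_matrix(iv, samples, vals),
    expression = expression_matrix(iv, samples, vals)
  )
}

#' @rdname read_matrix
#' @param m an assay matrix.
#' @export
write_matrix <- function(m, path) {
  df <- cbind(m$intervals[, c("chrom", "start", "end", "id")],
              as.data.frame(m$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ASSOC_COLS <- c("variant_id", "phenotype_id", "mode", "distance",
                "rho", "nominal_p", "perm_p")

#' Write / read an association table
#'
#' Associations are stored as TSV with columns `variant_id`,
#' `phenotype_id`, `mode`, `distance`, `rho`, `nominal_p`, `perm_p`,
#' stably sorted by `(phenotype_id, perm_p)`. All statistics must be
#' populated.
#'
#' @param records association record data frame (see [run_scan()]).
#' @param path file path.
#' @return Invisibly `path` (write) or the record data frame (read).
#' @export
write_associations <- function(records, path) {
  stopifnot(all(ASSOC_COLS %in% names(records)))
  rec <- records[, ASSOC_COLS, drop = FALSE]
  if (anyNA(rec))
    stop("association records contain missing statistics", call. = FALSE)
  rec <- rec[order(rec$phenotype_id, rec$perm_p, rec$variant_id), ,
             drop = FALSE]
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  out <- c(paste(ASSOC_COLS, collapse = "\t"),
           sprintf("%s\t%s\t%s\t%d\t%s\t%s\t%s",
                   rec$variant_id, rec$phenotype_id, rec$mode,
                   as.integer(rec$distance), fmt(rec$rho),
                   fmt(rec$nominal_p), fmt(rec$perm_p)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' @rdname write_associations
#' @export
read_associations <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  stopifnot(identical(names(df), ASSOC_COLS))
  df
}
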