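#' CpG island shores
#'
#' Extends each CpG island by `flank` bp on both sides (shores), clips
#' at position 0 and, when a genome is supplied, at the chromosome end,
#' and merges overlapping extended regions.
#'
#' @param islands a [feature_track()] or interval table of CpG islands.
#' @param flank shore width in bp (default 2,000).
#' @param genome optional named vector of chromosome lengths for
#'   right-clipping.
#' @return A [feature_track()] of merged island+shore regions.
#' @export
define_shores <- function(islands, flank = 2000L, genome = NULL) {
  iv <- track_intervals(islands)
  start <- pmax(0, iv$start - flank)
  end <- iv$end + flank
  if (!is.null(genome)) {
    L <- genome[iv$chrom]
    if (anyNA(L)) stop("island chromosome missing from genome", call. = FALSE)
    end <- pmin(end, L)
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end)))
  merged <- gintervals(as.character(GenomicRanges::seqnames(gr)),
                       GenomicRanges::start(gr) - 1L,
                       GenomicRanges::end(gr))
  name <- if (inherits(islands, "feature_track"))
    paste0(islands$name, "_shores") else "island_shores"
  feature_track(name, merged)
}

#' Fraction of query intervals overlapping a subject track
#'
#' Counts query intervals with at least `min_overlap` bp of
#' intersection against the subject set (1 bp intersection is the
#' working convention for region comparisons).
#'
#' @param query a [feature_track()] or interval table (non-empty).
#' @param subject a [feature_track()] or interval table.
#' @param min_overlap minimum intersection in bp.
#' @return List `(count, total, fraction)`.
#' @export
overlap_fraction <- function(query, subject, min_overlap = 1L) {
  qiv <- track_intervals(query)
  if (nrow(qiv) == 0L) stop("empty query set", call. = FALSE)
  count <- count_overlapping(qiv, subject, min_overlap)
  list(count = count, total = nrow(qiv), fraction = count / nrow(qiv))
}

#' Genic-context classification of a CNV
#'
#' Labels a CNV by the highest-priority overlapping biotype
#' (protein_coding > lncRNA > pseudogene), else `nongenic` ("gene
#' desert"). For genic CNVs the subgenic label is `exon` when any exon
#' of the chosen class is touched, `intron` when only intronic span is
#' touched, and `mixed` when, across genes, both occur. Any-bp overlap
#' decides membership.
#'
#' @param cnv single-row interval.
#' @param genes interval table with an extra `biotype` column
#'   (`protein_coding`, `lncRNA`, or `pseudogene`).
#' @param exons interval table with an extra `gene_id` column mapping
#'   each exon to its gene; exons must lie within their gene span.
#' @return List `(cnv_id, class, subgenic)` with `class` in
#'   gene/lncRNA/pseudogene/nongenic and `subgenic` in
#'   exon/intron/mixed/`NA`.
#' @export
classify_cnv_context <- function(cnv, genes, exons = NULL) {
  stopifnot("biotype" %in% names(genes))
  ov <- genes$chrom == cnv$chrom & genes$start < cnv$end &
    genes$end > cnv$start
  hit <- genes[ov, , drop = FALSE]
  if (nrow(hit) == 0L)
    return(list(cnv_id = cnv$id, class = "nongenic", subgenic = NA_character_))
  priority <- c(protein_coding = 1L, lncRNA = 2L, pseudogene = 3L)
  cls_bio <- names(priority)[min(priority[hit$biotype])]
  label <- c(protein_coding = "gene", lncRNA = "lncRNA",
             pseudogene = "pseudogene")[[cls_bio]]
  sel <- hit[hit$biotype == cls_bio, , drop = FALSE]
  exon_hit <- intron_hit <- FALSE
  for (gi in seq_len(nrow(sel))) {
    gex <- if (is.null(exons)) sel[0, ] else
      exons[exons$gene_id == sel$id[gi], , drop = FALSE]
    ex <- nrow(gex) > 0L && any(gex$chrom == cnv$chrom &
                                  gex$start < cnv$end & gex$end > cnv$start)
    if (ex) exon_hit <- TRUE else intron_hit <- TRUE
  }
  subgenic <- if (exon_hit && intron_hit) "mixed"
    else if (exon_hit) "exon" else "intron"
  list(cnv_id = cnv$id, class = label, subgenic = subgenic)
}

#' @rdname classify_cnv_context
#' @param cnvs interval table of CNVs.
#' @return For `classify_cnv_contexts`: data frame of labels, one row
#'   per CNV.
#' @export
classify_cnv_contexts <- function(cnvs, genes, exons = NULL) {
  cnvs <- gintervals(cnvs)
  rows <- lapply(seq_len(nrow(cnvs)), function(i)
    classify_cnv_context(cnvs[i, ], genes, exons))
  data.frame(cnv_id = vapply(rows, `[[`, "", "cnv_id"),
             class = vapply(rows, `[[`, "", "class"),
             subgenic = vapply(rows, function(r)
               if (is.na(r$subgenic)) NA_character_ else r$subgenic, ""),
             stringsAsFactors = FALSE)
}

#' Tag genes as imprinted
#'
#' Case-normalized intersection of significant-association gene ids
#' with an imprinted-gene catalog, with a provenance column naming the
#' source list.
#'
#' @param phenotype_genes character vector of gene ids from significant
#'   records.
#' @param imprinted either a character vector of imprinted gene ids or
#'   a data frame `(gene_id, source)`.
#' @param source label used when `imprinted` is a plain vector.
#' @return Data frame `(gene_id, source)` for the tagged subset (gene
#'   ids in their original spelling).
#' @export
tag_imprinted <- function(phenotype_genes, imprinted, source = "imprinted") {
  if (is.data.frame(imprinted)) {
    cat_ids <- imprinted$gene_id
    cat_src <- imprinted$source
  } else {
    cat_ids <- as.character(imprinted)
    cat_src <- rep(source, length(cat_ids))
  }
  idx <- match(toupper(phenotype_genes), toupper(cat_ids))
  hit <- !is.na(idx)
  out <- data.frame(gene_id = phenotype_genes[hit],
                    source = cat_src[idx[hit]],
                    stringsAsFactors = FALSE)
  out[!duplicated(out$gene_id), , drop = FALSE]
}
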