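# cRE definition and S-LDSC annotation partitioning.
#
# A cis-regulatory element (cRE) is an open chromatin region (OCR) that
# physically contacts a gene promoter through a chromatin loop: one loop
# anchor overlaps the OCR, the *other* anchor overlaps the promoter window.
# Contact through a single anchor (the anchor covering both the OCR and the
# promoter) is excluded: looping means contacting a distant promoter.

.anchor_df <- function(loops, which = 1) {
  data.frame(chrom = loops$chrom,
             start = loops[[paste0("start", which)]],
             end = loops[[paste0("end", which)]],
             stringsAsFactors = FALSE)
}

# overlap join: rows (query_idx, subject_idx)
.ov_pairs <- function(q, s) {
  if (!nrow(q) || !nrow(s)) return(data.frame(q = integer(), s = integer()))
  h <- GenomicRanges::findOverlaps(.as_granges(q), .as_granges(s))
  data.frame(q = S4Vectors::queryHits(h), s = S4Vectors::subjectHits(h))
}

#' Define cis-regulatory elements from OCRs, loops, and promoters
#'
#' An OCR becomes a cRE if it overlaps (>= 1 bp) one anchor of at least one
#' loop whose partner anchor overlaps at least one promoter window; the cRE's
#' contacted genes are the union of all genes reached this way. With
#' `require_open_promoter = TRUE` (default) only promoters that themselves
#' overlap an OCR of the same cell type count as contact targets. An OCR that
#' overlaps a promoter window may still be a cRE for *other* genes' promoters
#' reached through loops.
#'
#' Exact duplicate loops (identical anchor coordinates) are deduplicated here,
#' with the count reported via message and the `"n_duplicate_loops"` attribute.
#'
#' @param ocrs Peaks data.frame from [read_bed()] (one cell type).
#' @param loops Loops data.frame from [read_loops()] (same cell type).
#' @param promoters Promoter windows from [make_promoters()].
#' @param require_open_promoter Restrict contacts to promoters overlapping an
#'   OCR of the same cell type.
#' @return Long-format data.frame with one row per (cRE, gene) contact:
#'   `cre_id`, `cell_type`, `chrom`, `start`, `end`, `gene_id`, `loop_ids`
#'   (comma-joined), `n_loops`.
#' @export
define_cres <- function(ocrs, loops, promoters, require_open_promoter = TRUE) {
  cts <- unique(c(ocrs$cell_type, loops$cell_type))
  cts <- cts[!is.na(cts)]
  if (length(cts) > 1)
    stop("define_cres expects a single cell type, got: ",
         paste(cts, collapse = ", "))
  cell_type <- if (length(cts)) cts else NA_character_
  empty <- data.frame(cre_id = character(), cell_type = character(),
                      chrom = character(), start = integer(), end = integer(),
                      gene_id = character(), loop_ids = character(),
                      n_loops = integer(), stringsAsFactors = FALSE)
  if (!nrow(ocrs) || !nrow(loops) || !nrow(promoters)) return(empty)

  key <- paste(loops$chrom, loops$start1, loops$end1,
               loops$start2, loops$end2)
  dup <- duplicated(key)
  if (any(dup))
    message("define_cres: deduplicated ", sum(dup), " identical loop(s)")
  loops <- loops[!dup, , drop = FALSE]

  prom <- promoters
  if (require_open_promoter) {
    keep <- unique(.ov_pairs(prom, ocrs)$q)
    prom <- prom[keep, , drop = FALSE]
  }
  if (!nrow(prom)) return(empty)

  a1 <- .anchor_df(loops, 1)
  a2 <- .anchor_df(loops, 2)
  contacts <- list()
  for (orient in 1:2) {
    ocr_anchor <- if (orient == 1) a1 else a2
    prom_anchor <- if (orient == 1) a2 else a1
    po <- .ov_pairs(ocrs, ocr_anchor)   # q = ocr row, s = loop row
    pp <- .ov_pairs(prom, prom_anchor)  # q = promoter row, s = loop row
    if (!nrow(po) || !nrow(pp)) next
    m <- merge(po, pp, by = "s")        # join on loop
    if (!nrow(m)) next
    contacts[[orient]] <- data.frame(ocr = m$q.x, loop = m$s,
                                     gene = prom$gene_id[m$q.y],
                                     stringsAsFactors = FALSE)
  }
  if (!length(contacts)) return(empty)
  cc <- unique(do.call(rbind, contacts))
  cc$cre_id <- ocrs$peak_id[cc$ocr]
  cc$loop_id <- loops$loop_id[cc$loop]

  keyg <- paste(cc$cre_id, cc$gene, sep = "\r")
  agg <- split(cc, keyg)
  rows <- lapply(agg, function(g) {
    i <- g$ocr[1]
    lids <- sort(unique(g$loop_id))
    data.frame(cre_id = g$cre_id[1], cell_type = cell_type,
               chrom = ocrs$chrom[i], start = ocrs$start[i],
               end = ocrs$end[i], gene_id = g$gene[1],
               loop_ids = paste(lids, collapse = ","),
               n_loops = length(lids), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$chrom, out$start, out$cre_id, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_duplicate_loops") <- sum(dup)
  out
}

#' Partition open chromatin into the five S-LDSC annotation categories
#'
#' The five region sets per cell type: (1) `ALL_OCR`, every peak; (2)
#' `PROMOTER_OCR`, peaks overlapping any promoter window; (3) `CRE`,
#' promoter-contacting peaks; (4) `CRE_FLANK500`, cRE peaks extended by
#' `flank` bp each side and merged where overlapping; (5)
#' `NON_CRE_NON_PROM`, peaks that are neither promoter-overlapping nor cREs —
#' the negative control. Categories (2), (3) and (5) cover (1); (5) is
#' disjoint from (2) and (3); categories are otherwise not mutually exclusive.
#'
#' @param ocrs Peaks data.frame (one cell type).
#' @param cres Output of [define_cres()] on the same peaks.
#' @param promoters Promoter windows.
#' @param flank Non-negative extension for `CRE_FLANK500`, bp.
#' @return An `annotation_partition`: list with `cell_type` and `categories`
#'   (a named list of interval data.frames).
#' @export
partition_annotations <- function(ocrs, cres, promoters, flank = 500) {
  if (flank < 0) stop("flank must be >= 0")
  prom_hit <- rep(FALSE, nrow(ocrs))
  prom_hit[unique(.ov_pairs(ocrs, promoters)$q)] <- TRUE
  is_cre <- ocrs$peak_id %in% cres$cre_id
  cols <- c("chrom", "start", "end", "peak_id")
  cre_peaks <- ocrs[is_cre, cols, drop = FALSE]
  flanked <- cre_peaks
  if (nrow(flanked)) {
    flanked$start <- pmax(flanked$start - as.integer(flank), 0L)
    flanked$end <- flanked$end + as.integer(flank)
    flanked <- merge_intervals(flanked)
    flanked$peak_id <- sprintf("flank_%d", seq_len(nrow(flanked)))
  }
  categories <- list(
    ALL_OCR = ocrs[, cols, drop = FALSE],
    PROMOTER_OCR = ocrs[prom_hit, cols, drop = FALSE],
    CRE = cre_peaks,
    CRE_FLANK500 = flanked,
    NON_CRE_NON_PROM = ocrs[!prom_hit & !is_cre, cols, drop = FALSE]
  )
  structure(list(cell_type = ocrs$cell_type[1], categories = categories),
            class = "annotation_partition")
}

#' Export per-variant annotation membership in LDSC .annot layout
#'
#' Marks each template variant 1/0 by whether its position (a 0-based point)
#' falls inside an interval of the chosen category under the half-open rule:
#' `start <= bp < end`. Output row order equals template order.
#'
#' @param partition An `annotation_partition` from [partition_annotations()].
#' @param template data.frame sorted by `chrom`, `bp` with columns `chrom`,
#'   `bp` (0-based point), `snp`, `cm`.
#' @param category Category name, e.g. `"CRE"`.
#' @param path Optional output path; written gzip-compressed when it ends in
#'   `.gz`, plain TSV otherwise.
#' @return data.frame with columns `CHR`, `BP`, `SNP`, `CM`, `ANNOT`.
#' @export
export_ldsc_annot <- function(partition, template, category, path = NULL) {
  stopifnot(inherits(partition, "annotation_partition"))
  if (!category %in% names(partition$categories))
    stop("unknown category: ", category)
  ord <- order(template$chrom, template$bp)
  if (!identical(ord, seq_len(nrow(template))))
    stop("variant template must be sorted by chrom, bp")
  ints <- partition$categories[[category]]
  annot <- integer(nrow(template))
  if (nrow(ints) && nrow(template)) {
    h <- GenomicRanges::findOverlaps(
      .points_granges(template$chrom, template$bp), .as_granges(ints))
    annot[unique(S4Vectors::queryHits(h))] <- 1L
  }
  out <- data.frame(CHR = template$chrom, BP = template$bp,
                    SNP = template$snp, CM = template$cm, ANNOT = annot,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  out
}
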