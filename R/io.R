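# Readers/writers for the plain-text interchange formats the pipeline consumes:
# BED peaks, ibed/BEDPE loops, TSS tables, chrom sizes, summary-statistic TSVs.

.read_tsv <- function(path, header = TRUE, ...) {
  utils::read.table(path, header = header, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE, ...)
}

#' Read ATAC-seq peaks from a BED file
#'
#' BED coordinates are 0-based half-open and kept as such. Peak identifiers
#' come from column 4 when present, otherwise `chrom:start-end`.
#'
#' @param path BED3/BED4 file (tab-separated, no header).
#' @param cell_type Cell-type label attached to every peak.
#' @return data.frame of peaks: `chrom`, `start`, `end`, `peak_id`, `cell_type`.
#' @export
read_bed <- function(path, cell_type) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), peak_id = character(),
                      cell_type = character(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("BED line ", bad[1], ": start >= end")
  peak_id <- ifelse(nf >= 4L,
                    vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "", ""),
                    paste0(chrom, ":", start, "-", end))
  data.frame(chrom = chrom, start = start, end = end, peak_id = peak_id,
             cell_type = cell_type, stringsAsFactors = FALSE)
}

#' Write peaks to BED4
#'
#' @param peaks data.frame with `chrom`, `start`, `end`, `peak_id`.
#' @param path Output path.
#' @export
write_bed <- function(peaks, path) {
  df <- peaks[, c("chrom", "start", "end", "peak_id")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.ibed_cols <- c("bait_chr", "bait_start", "bait_end", "bait_name",
                "otherEnd_chr", "otherEnd_start", "otherEnd_end",
                "otherEnd_name", "N_reads", "score")

#' Read promoter-interaction loops (CHiCAGO ibed or BEDPE)
#'
#' Each line is one physical contact between two anchors. Inter-chromosomal
#' lines are dropped (the pipeline only uses intra-chromosomal loops); the
#' number dropped is reported via a message and the `"n_interchrom_dropped"`
#' attribute. Duplicate lines are retained with distinct loop ids —
#' deduplication is an explicit step in [define_cres()].
#'
#' @param path Loop file. ibed is tab-separated with the CHiCAGO header
#'   (`bait_chr ... score`); BEDPE has >= 6 unnamed columns.
#' @param format `"ibed"` or `"bedpe"`.
#' @param cell_type Cell-type label.
#' @param source Assay label, `"pcc"` (promoter Capture-C) or `"hic"`.
#' @return data.frame of loops: `loop_id`, `cell_type`, `source`, `chrom`,
#'   `start1`, `end1`, `start2`, `end2`, `score`.
#' @export
read_loops <- function(path, format = c("ibed", "bedpe"), cell_type,
                       source = c("pcc", "hic")) {
  format <- match.arg(format)
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "ibed") {
    df <- .read_tsv(path, header = TRUE)
    miss <- setdiff(.ibed_cols[1:8], names(df))
    if (length(miss))
      stop("ibed format error, missing column(s): ",
           paste(miss, collapse = ", "))
    raw <- data.frame(chrom1 = df$bait_chr, start1 = df$bait_start,
                      end1 = df$bait_end, chrom2 = df$otherEnd_chr,
                      start2 = df$otherEnd_start, end2 = df$otherEnd_end,
                      score = if ("score" %in% names(df)) df$score else NA_real_,
                      stringsAsFactors = FALSE)
  } else {
    df <- .read_tsv(path, header = FALSE)
    if (ncol(df) < 6) stop("BEDPE format error: fewer than 6 columns")
    raw <- data.frame(chrom1 = df[[1]], start1 = df[[2]], end1 = df[[3]],
                      chrom2 = df[[4]], start2 = df[[5]], end2 = df[[6]],
                      score = if (ncol(df) >= 8) suppressWarnings(as.numeric(df[[8]]))
                              else NA_real_,
                      stringsAsFactors = FALSE)
  }
  if (!nrow(raw)) stop("no loop lines in ", path)
  inter <- raw$chrom1 != raw$chrom2
  n_drop <- sum(inter)
  if (n_drop) message("read_loops: dropped ", n_drop,
                      " inter-chromosomal line(s)")
  raw <- raw[!inter, , drop = FALSE]
  if (!nrow(raw)) stop("no intra-chromosomal loops in ", path)
  out <- data.frame(loop_id = sprintf("%s_%s_L%d", cell_type, source,
                                      seq_len(nrow(raw))),
                    cell_type = cell_type, source = source,
                    chrom = raw$chrom1,
                    start1 = as.integer(raw$start1), end1 = as.integer(raw$end1),
                    start2 = as.integer(raw$start2), end2 = as.integer(raw$end2),
                    score = raw$score, stringsAsFactors = FALSE)
  attr(out, "n_interchrom_dropped") <- n_drop
  out
}

#' Write loops to ibed
#'
#' @param loops data.frame as returned by [read_loops()].
#' @param path Output path.
#' @export
write_ibed <- function(loops, path) {
  df <- data.frame(bait_chr = loops$chrom, bait_start = loops$start1,
                   bait_end = loops$end1, bait_name = loops$loop_id,
                   otherEnd_chr = loops$chrom, otherEnd_start = loops$start2,
                   otherEnd_end = loops$end2,
                   otherEnd_name = paste0(loops$loop_id, "_oe"),
                   N_reads = 0L,
                   score = ifelse(is.na(loops$score), 0, loops$score))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene/TSS annotation table
#'
#' @param path TSV with header columns `gene_id`, `gene_name`, `chrom`,
#'   `tss` (1-based), `strand`.
#' @return data.frame with those columns.
#' @export
read_tss_table <- function(path) {
  df <- .read_tsv(path, header = TRUE)
  need <- c("gene_id", "gene_name", "chrom", "tss", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("TSS table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$tss < 1)) stop("TSS positions must be >= 1")
  df[, need]
}

#' Read chromosome sizes
#'
#' @param path Two-column TSV (chrom, size), no header.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- .read_tsv(path, header = FALSE)
  stats::setNames(as.integer(df[[2]]), as.character(df[[1]]))
}

#' Read and standardize GWAS/eQTL summary statistics
#'
#' Applies a declared column mapping so arbitrarily-labelled TSVs can be
#' munged into one schema. Odds ratios are converted to log-odds
#' (`beta = ln(OR)`). Rows with `se <= 0` or missing position are dropped;
#' drop counts are reported via message and the `"n_dropped_se"` /
#' `"n_dropped_pos"` attributes.
#'
#' @param path TSV with a header.
#' @param columns Named list mapping standard field names (`variant`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `se`, and one of `beta` or `or`;
#'   optionally `pvalue`, `maf`, `n`) to the file's column names. Defaults to
#'   identity naming.
#' @return data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, and `pvalue`/`maf`/`n`
#'   when mapped.
#' @export
read_sumstats <- function(path, columns = list()) {
  defaults <- list(variant = "variant", chrom = "chrom", pos = "pos",
                   effect_allele = "effect_allele",
                   other_allele = "other_allele",
                   beta = "beta", se = "se")
  columns <- utils::modifyList(defaults, columns)
  df <- .read_tsv(path, header = TRUE)
  mandatory <- c("variant", "chrom", "pos", "effect_allele", "other_allele",
                 "se")
  for (f in mandatory) {
    if (is.null(columns[[f]]) || !(columns[[f]] %in% names(df)))
      stop("summary-statistics configuration error: no column mapped for '",
           f, "'")
  }
  has_beta <- !is.null(columns$beta) && columns$beta %in% names(df)
  has_or <- !is.null(columns$or) && columns$or %in% names(df)
  if (!has_beta && !has_or)
    stop("summary-statistics configuration error: need a 'beta' or 'or' column")
  beta <- if (has_beta) as.numeric(df[[columns$beta]])
          else log(as.numeric(df[[columns$or]]))
  out <- data.frame(variant_id = as.character(df[[columns$variant]]),
                    chrom = as.character(df[[columns$chrom]]),
                    pos = suppressWarnings(as.integer(df[[columns$pos]])),
                    effect_allele = toupper(df[[columns$effect_allele]]),
                    other_allele = toupper(df[[columns$other_allele]]),
                    beta = beta,
                    se = as.numeric(df[[columns$se]]),
                    stringsAsFactors = FALSE)
  for (f in c("pvalue", "maf", "n"))
    if (!is.null(columns[[f]]) && columns[[f]] %in% names(df))
      out[[f]] <- as.numeric(df[[columns[[f]]]])
  bad_pos <- is.na(out$pos)
  bad_se <- !bad_pos & (is.na(out$se) | out$se <= 0)
  if (any(bad_pos)) message("read_sumstats: dropped ", sum(bad_pos),
                            " row(s) with missing position")
  if (any(bad_se)) message("read_sumstats: dropped ", sum(bad_se),
                           " row(s) with non-positive SE")
  res <- out[!(bad_pos | bad_se), , drop = FALSE]
  attr(res, "n_dropped_pos") <- sum(bad_pos)
  attr(res, "n_dropped_se") <- sum(bad_se)
  res
}

#' Read a plain-text gene list (one symbol per line)
#'
#' @param path Text file; blank lines and `#` comments ignored.
#' @return Character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
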