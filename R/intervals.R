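#' @importFrom GenomicRanges GRanges findOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# All genomic coordinates in this package are 0-based half-open [start, end),
# the BED convention. 1-based TSS inputs are converted on read. Variant
# positions are 0-based points (dbSNP-style): position p lies inside
# [start, end) iff start <= p < end.

.check_intervals <- function(df, what = "intervals") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(!nzchar(df$chrom)))
      stop(what, ": empty chromosome name")
    if (any(df$start < 0))
      stop(what, ": negative start coordinate")
    bad <- which(df$start >= df$end)
    if (length(bad))
      stop(what, ": start >= end at row ", bad[1])
  }
  invisible(df)
}

# data.frame (0-based half-open) -> GRanges (1-based closed)
.as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# 0-based point positions -> width-1 GRanges such that overlap with
# .as_granges(df) means start <= pos < end (half-open membership)
.points_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1L,
                                                 end = pos + 1L))
}

#' Test whether two genomic intervals overlap
#'
#' Intervals are 0-based half-open; overlap requires at least one shared base
#' on the same chromosome, so abutting intervals (`a$end == b$start`) do not
#' overlap. Vectorized over rows (recycled as usual).
#'
#' @param a,b data.frames (or single-row lists) with `chrom`, `start`, `end`.
#' @return Logical vector.
#' @examples
#' a <- data.frame(chrom = "chr1", start = 100, end = 200)
#' b <- data.frame(chrom = "chr1", start = 200, end = 300)
#' overlaps(a, b)  # FALSE: half-open abutment
#' @export
overlaps <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  as.character(a$chrom) == as.character(b$chrom) &
    a$start < b$end & b$start < a$end
}

#' Merge overlapping intervals
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return data.frame of merged intervals, sorted by chrom then start.
#' @export
merge_intervals <- function(df) {
  .check_intervals(df, "merge_intervals input")
  if (!nrow(df))
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  red <- GenomicRanges::reduce(.as_granges(df))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1L,
                    end   = GenomicRanges::end(red),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Build promoter windows around transcription start sites
#'
#' The promoter of a gene is the window from `upstream` bp upstream to
#' `downstream` bp downstream of its TSS (defaults \eqn{-1500/+500}),
#' orientation following the gene strand. Windows are clamped at chromosome
#' boundaries rather than erroring, so genes near contig edges get truncated
#' promoters.
#'
#' @param genes data.frame with `gene_id`, `gene_name`, `chrom`, `tss`
#'   (1-based position), `strand` ("+" or "-").
#' @param upstream,downstream Non-negative window extents in bp.
#' @param chrom_sizes Named integer vector (or two-column data.frame
#'   chrom/size) giving chromosome lengths.
#' @return data.frame with one promoter window per input row: `gene_id`,
#'   `gene_name`, `chrom`, `start`, `end` (0-based half-open), `strand`, `tss`.
#' @export
make_promoters <- function(genes, upstream = 1500, downstream = 500,
                           chrom_sizes) {
  stopifnot(upstream >= 0, downstream >= 0)
  if (is.data.frame(chrom_sizes))
    chrom_sizes <- stats::setNames(chrom_sizes[[2]],
                                   as.character(chrom_sizes[[1]]))
  unknown <- setdiff(unique(as.character(genes$chrom)), names(chrom_sizes))
  if (length(unknown))
    stop("chromosome(s) absent from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  if (any(genes$tss < 1)) stop("TSS positions must be >= 1")
  tss0 <- genes$tss - 1L                       # 0-based TSS base
  plus <- genes$strand == "+"
  start <- ifelse(plus, tss0 - upstream, tss0 - downstream + 1L)
  end   <- ifelse(plus, tss0 + downstream, tss0 + upstream + 1L)
  len <- unname(chrom_sizes[as.character(genes$chrom)])
  start <- pmax(start, 0L)
  end <- pmin(end, len)
  data.frame(gene_id = genes$gene_id,
             gene_name = if (!is.null(genes$gene_name)) genes$gene_name
                         else genes$gene_id,
             chrom = as.character(genes$chrom),
             start = as.integer(start), end = as.integer(end),
             strand = genes$strand, tss = genes$tss,
             stringsAsFactors = FALSE)
}
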