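# Variant-to-gene mapping: LD-proxy filtering and placement of accessible
# proxies within each cell type's cRE landscape.

.default_mhc <- function() {
  data.frame(chrom = "chr6", start = 25000000L, end = 34000000L)
}

.point_in_interval <- function(chrom, pos, interval) {
  as.character(chrom) == as.character(interval$chrom) &
    pos >= interval$start & pos < interval$end
}

#' Filter LD proxies for variant-to-gene mapping
#'
#' Keeps proxies with \eqn{r^2 \ge} `r2_min` (default 0.8), removes any proxy
#' inside the MHC window, removes every proxy of a sentinel that itself lies
#' inside the MHC, and adds each sentinel as its own proxy with
#' \eqn{r^2 = 1} when absent from the table (LD is reflexive).
#'
#' @param proxies data.frame with `trait`, `sentinel`, `proxy`, `chrom`,
#'   `pos` (0-based point), `r2`.
#' @param sentinels Optional data.frame with `trait`, `variant_id`, `chrom`,
#'   `pos`; needed for MHC sentinel exclusion and self-proxy completion.
#' @param r2_min LD threshold.
#' @param mhc Excluded region as a one-row data.frame (`chrom`, `start`,
#'   `end`); default chr6:25,000,000-34,000,000 (GRCh38). `NULL` disables.
#' @return Filtered proxy data.frame; drop counts attached as attributes
#'   `"n_dropped_r2"` and `"n_dropped_mhc"`.
#' @export
filter_proxies <- function(proxies, sentinels = NULL, r2_min = 0.8,
                           mhc = .default_mhc()) {
  if (any(proxies$r2 < 0 | proxies$r2 > 1))
    stop("r2 outside [0, 1]")
  if (!is.null(sentinels)) {
    key_have <- unique(paste(proxies$trait, proxies$sentinel,
                             proxies$proxy)[proxies$proxy == proxies$sentinel])
    key_sent <- paste(sentinels$trait, sentinels$variant_id,
                      sentinels$variant_id)
    add <- sentinels[!(key_sent %in% key_have), , drop = FALSE]
    if (nrow(add)) {
      proxies <- rbind(proxies,
                       data.frame(trait = add$trait, sentinel = add$variant_id,
                                  proxy = add$variant_id, chrom = add$chrom,
                                  pos = add$pos, r2 = 1.0,
                                  stringsAsFactors = FALSE))
    }
  }
  drop_r2 <- proxies$r2 < r2_min
  n_r2 <- sum(drop_r2)
  out <- proxies[!drop_r2, , drop = FALSE]
  n_mhc <- 0L
  if (!is.null(mhc)) {
    in_mhc <- .point_in_interval(out$chrom, out$pos, mhc)
    bad_sent <- character()
    if (!is.null(sentinels)) {
      sent_in <- .point_in_interval(sentinels$chrom, sentinels$pos, mhc)
      bad_sent <- sentinels$variant_id[sent_in]
    }
    drop_m <- in_mhc | out$sentinel %in% bad_sent
    n_mhc <- sum(drop_m)
    out <- out[!drop_m, , drop = FALSE]
  }
  if (n_r2 + n_mhc > 0)
    message("filter_proxies: dropped ", n_r2, " low-r2 and ", n_mhc,
            " MHC proxy row(s)")
  rownames(out) <- NULL
  attr(out, "n_dropped_r2") <- n_r2
  attr(out, "n_dropped_mhc") <- n_mhc
  out
}

#' Map accessible proxies to target genes through cRE-promoter contacts
#'
#' For each (proxy, cell type), if the proxy position falls inside a cRE of
#' that cell type, one variant-gene pair is emitted per gene whose promoter
#' the cRE contacts. Pairs are deduplicated on
#' (trait, proxy, cell type, gene); when a proxy sits in several overlapping
#' cREs contacting the same gene, the surviving pair carries the union of
#' supporting cRE and loop ids. Proxies in no cRE emit nothing.
#'
#' @param proxies Filtered proxies from [filter_proxies()].
#' @param cres cRE contact table from [define_cres()]; rows from several cell
#'   types may be concatenated.
#' @return data.frame with `trait`, `sentinel`, `proxy`, `chrom`, `pos`,
#'   `cell_type`, `cre_id`, `gene_id`, `loop_ids`.
#' @export
map_variants_to_genes <- function(proxies, cres) {
  empty <- data.frame(trait = character(), sentinel = character(),
                      proxy = character(), chrom = character(),
                      pos = integer(), cell_type = character(),
                      cre_id = character(), gene_id = character(),
                      loop_ids = character(), stringsAsFactors = FALSE)
  if (!nrow(proxies) || !nrow(cres)) return(empty)
  h <- GenomicRanges::findOverlaps(
    .points_granges(proxies$chrom, proxies$pos), .as_granges(cres))
  if (!length(h)) return(empty)
  pi <- S4Vectors::queryHits(h); ci <- S4Vectors::subjectHits(h)
  hits <- data.frame(trait = proxies$trait[pi],
                     sentinel = proxies$sentinel[pi],
                     proxy = proxies$proxy[pi],
                     chrom = proxies$chrom[pi], pos = proxies$pos[pi],
                     cell_type = cres$cell_type[ci],
                     cre_id = cres$cre_id[ci], gene_id = cres$gene_id[ci],
                     loop_ids = cres$loop_ids[ci], stringsAsFactors = FALSE)
  key <- paste(hits$trait, hits$proxy, hits$cell_type, hits$gene_id,
               sep = "\r")
  parts <- split(hits, key)
  rows <- lapply(parts, function(g) {
    g1 <- g[1, , drop = FALSE]
    g1$sentinel <- paste(sort(unique(g$sentinel)), collapse = ",")
    g1$cre_id <- paste(sort(unique(g$cre_id)), collapse = ",")
    lids <- sort(unique(unlist(strsplit(g$loop_ids, ",", fixed = TRUE))))
    g1$loop_ids <- paste(lids, collapse = ",")
    g1
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$trait, out$chrom, out$pos, out$cell_type,
                   out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distinct target genes per variant and cell type
#'
#' @param pairs Variant-gene pair table from [map_variants_to_genes()].
#' @return List with `counts` (data.frame `proxy`, `cell_type`, `n_genes`)
#'   and `mean_genes` (arithmetic mean over (proxy, cell type) observations).
#' @export
genes_per_variant <- function(pairs) {
  if (!nrow(pairs)) stop("empty pair table")
  key <- paste(pairs$proxy, pairs$cell_type, sep = "\r")
  tab <- tapply(pairs$gene_id, key, function(g) length(unique(g)))
  ks <- strsplit(names(tab), "\r", fixed = TRUE)
  counts <- data.frame(proxy = vapply(ks, `[[`, "", 1L),
                       cell_type = vapply(ks, `[[`, "", 2L),
                       n_genes = as.integer(tab), stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  list(counts = counts, mean_genes = mean(counts$n_genes))
}
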