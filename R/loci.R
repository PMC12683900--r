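# Construction of non-overlapping LD-merged loci around GWAS sentinels, and
# locus-level eGene extraction / V2G-eQTL concordance.

#' Build non-overlapping loci from sentinels and their LD proxies
#'
#' Three steps: (1) per sentinel, a candidate region spanning the sentinel
#' position, its proxy span, and the proxy span extended by `flank` bp each
#' side; (2) overlapping candidates merged into non-redundant regions; (3) a
#' region holding several sentinels is kept merged only if the sentinels form
#' one connected component of the pairwise \eqn{r^2 \ge} `r2_merge` graph —
#' otherwise it is split at the midpoint between the adjacent low-LD groups'
#' proxy-span boundaries. Output loci are pairwise non-overlapping.
#'
#' @param sentinels data.frame with `variant_id`, `chrom`, `pos` (0-based
#'   point); `trait` optional. Duplicate variant ids (e.g. one sentinel
#'   reported for several traits) are collapsed.
#' @param proxies data.frame with `sentinel`, `chrom`, `pos`; every sentinel
#'   must appear (possibly only as its own proxy).
#' @param flank Extension of the proxy span, bp (default 250,000).
#' @param ld_r2 Symmetric matrix of pairwise sentinel \eqn{r^2}, dimnames =
#'   sentinel variant ids. Required whenever a merged region holds more than
#'   one sentinel; a missing entry for a co-resident pair is an error naming
#'   the pair.
#' @param r2_merge LD threshold for keeping co-resident sentinels merged.
#' @return data.frame of loci: `locus_id`, `chrom`, `start`, `end`,
#'   `sentinels` (comma-joined), `n_sentinels`, `provenance`.
#' @export
build_loci <- function(sentinels, proxies, flank = 250000, ld_r2 = NULL,
                       r2_merge = 0.8) {
  sent <- sentinels[!duplicated(sentinels$variant_id), , drop = FALSE]
  missing_prox <- setdiff(sent$variant_id, proxies$sentinel)
  if (length(missing_prox))
    stop("sentinel(s) without proxies: ",
         paste(missing_prox, collapse = ", "))
  span <- do.call(rbind, lapply(seq_len(nrow(sent)), function(i) {
    id <- sent$variant_id[i]
    pp <- proxies$pos[proxies$sentinel == id]
    lo <- min(c(pp, sent$pos[i])); hi <- max(c(pp, sent$pos[i]))
    data.frame(sentinel = id, chrom = sent$chrom[i],
               span_lo = lo, span_hi = hi,
               start = max(0L, lo - as.integer(flank)),
               end = hi + 1L + as.integer(flank),
               stringsAsFactors = FALSE)
  }))
  regions <- merge_intervals(span[, c("chrom", "start", "end")])
  h <- GenomicRanges::findOverlaps(.as_granges(span), .as_granges(regions))
  span$region <- NA_integer_
  span$region[S4Vectors::queryHits(h)] <- S4Vectors::subjectHits(h)

  loci <- list()
  for (ri in seq_len(nrow(regions))) {
    mem <- span[span$region == ri, , drop = FALSE]
    reg <- regions[ri, ]
    if (nrow(mem) == 1) {
      loci[[length(loci) + 1]] <-
        data.frame(chrom = reg$chrom, start = reg$start, end = reg$end,
                   sentinels = mem$sentinel, n_sentinels = 1L,
                   provenance = "single", stringsAsFactors = FALSE)
      next
    }
    if (is.null(ld_r2))
      stop("region with ", nrow(mem), " sentinels on ", reg$chrom,
           " requires an ld_r2 matrix")
    ids <- mem$sentinel
    for (a in seq_along(ids)) for (b in seq_along(ids)) {
      if (a < b && (!all(c(ids[a], ids[b]) %in% rownames(ld_r2)) ||
                    is.na(ld_r2[ids[a], ids[b]])))
        stop("missing LD entry for co-resident sentinels ",
             ids[a], " and ", ids[b])
    }
    adj <- ld_r2[ids, ids, drop = FALSE] >= r2_merge
    diag(adj) <- TRUE
    comp <- .connected_components(adj)
    if (max(comp) == 1) {
      loci[[length(loci) + 1]] <-
        data.frame(chrom = reg$chrom, start = reg$start, end = reg$end,
                   sentinels = paste(sort(ids), collapse = ","),
                   n_sentinels = length(ids),
                   provenance = sprintf("merged_r2>=%.2f", r2_merge),
                   stringsAsFactors = FALSE)
      next
    }
    # order components along the chromosome by proxy-span midpoint, then
    # split between consecutive groups' proxy-span boundaries
    glo <- tapply(mem$span_lo, comp, min)
    ghi <- tapply(mem$span_hi, comp, max)
    ord <- order((as.numeric(glo) + as.numeric(ghi)) / 2)
    cuts <- reg$start
    for (k in seq_len(length(ord) - 1)) {
      left_hi <- ghi[[ord[k]]] + 1          # end of left group's proxy span
      right_lo <- glo[[ord[k + 1]]]         # start of right group's span
      s <- floor((left_hi + right_lo) / 2)
      # keep cuts strictly increasing and leave room for remaining groups
      s <- min(max(s, cuts[length(cuts)] + 1),
               reg$end - (length(ord) - k))
      cuts <- c(cuts, s)
    }
    cuts <- c(cuts, reg$end)
    for (k in seq_len(length(ord))) {
      members <- sort(ids[comp == ord[k]])
      loci[[length(loci) + 1]] <-
        data.frame(chrom = reg$chrom, start = cuts[k], end = cuts[k + 1],
                   sentinels = paste(members, collapse = ","),
                   n_sentinels = length(members),
                   provenance = sprintf("split_r2<%.2f_group%d", r2_merge, k),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, loci)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(locus_id = sprintf("locus_%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# connected components of a logical adjacency matrix (BFS)
.connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v]) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Extract locus eGenes from an eQTL association table
#'
#' An eGene is kept for a locus when at least one of its eQTL variants lies
#' inside the locus, passes the FDR cut, is (optionally) one of the locus
#' sentinels' high-LD proxies, and the gene lies on the locus chromosome.
#'
#' @param loci Locus table from [build_loci()].
#' @param eqtl data.frame with `variant_id`, `chrom`, `pos`, `gene_id`,
#'   and either `fdr` or `pvalue` (BH-corrected per `cell_type`/`dataset`
#'   stratum when only `pvalue` is present); optional `gene_chrom` (defaults
#'   to the variant chromosome), `cell_type`, `dataset`.
#' @param fdr_max Significance cut on FDR (default 0.05).
#' @param require_same_chrom Drop trans genes on another chromosome.
#' @param require_high_ld_variant Restrict to variants that are high-LD
#'   proxies of the locus sentinels (needs `proxies`).
#' @param proxies Filtered proxy table (used when `require_high_ld_variant`).
#' @param fdr_rule `"significant"` keeps FDR <= `fdr_max`; `"literal"` keeps
#'   FDR > `fdr_max` (the verbatim reading of a likely typo in the source
#'   protocol; not recommended).
#' @return data.frame with `locus_id`, `gene_id`, `cell_type`, `dataset`,
#'   `best_variant`, `min_fdr`.
#' @export
assign_egenes <- function(loci, eqtl, fdr_max = 0.05,
                          require_same_chrom = TRUE,
                          require_high_ld_variant = TRUE, proxies = NULL,
                          fdr_rule = c("significant", "literal")) {
  fdr_rule <- match.arg(fdr_rule)
  eq <- eqtl
  if (is.null(eq$fdr)) {
    if (is.null(eq$pvalue))
      stop("eqtl table needs an 'fdr' or 'pvalue' column")
    strat <- paste(if (!is.null(eq$dataset)) eq$dataset else "",
                   if (!is.null(eq$cell_type)) eq$cell_type else "")
    eq$fdr <- stats::ave(eq$pvalue, strat,
                         FUN = function(p) stats::p.adjust(p, "BH"))
  }
  if (is.null(eq$gene_chrom)) eq$gene_chrom <- eq$chrom
  if (is.null(eq$cell_type)) eq$cell_type <- NA_character_
  if (is.null(eq$dataset)) eq$dataset <- NA_character_
  keep_fdr <- if (fdr_rule == "significant") eq$fdr <= fdr_max
              else eq$fdr > fdr_max
  eq <- eq[keep_fdr, , drop = FALSE]
  empty <- data.frame(locus_id = character(), gene_id = character(),
                      cell_type = character(), dataset = character(),
                      best_variant = character(), min_fdr = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(eq) || !nrow(loci)) return(empty)
  h <- GenomicRanges::findOverlaps(.points_granges(eq$chrom, eq$pos),
                                   .as_granges(loci))
  if (!length(h)) return(empty)
  hits <- data.frame(eq_row = S4Vectors::queryHits(h),
                     locus_row = S4Vectors::subjectHits(h))
  hits$locus_id <- loci$locus_id[hits$locus_row]
  rows <- eq[hits$eq_row, , drop = FALSE]
  rows$locus_id <- hits$locus_id
  rows$locus_chrom <- loci$chrom[hits$locus_row]
  rows$locus_sent <- loci$sentinels[hits$locus_row]
  if (require_same_chrom)
    rows <- rows[rows$gene_chrom == rows$locus_chrom, , drop = FALSE]
  if (require_high_ld_variant) {
    if (is.null(proxies))
      stop("require_high_ld_variant = TRUE needs a proxies table")
    ok <- vapply(seq_len(nrow(rows)), function(i) {
      sents <- strsplit(rows$locus_sent[i], ",", fixed = TRUE)[[1]]
      rows$variant_id[i] %in%
        proxies$proxy[proxies$sentinel %in% sents]
    }, logical(1))
    rows <- rows[ok, , drop = FALSE]
  }
  if (!nrow(rows)) return(empty)
  key <- paste(rows$locus_id, rows$gene_id, rows$cell_type, rows$dataset,
               sep = "\r")
  parts <- split(rows, key)
  out <- do.call(rbind, lapply(parts, function(g) {
    b <- which.min(g$fdr)
    data.frame(locus_id = g$locus_id[1], gene_id = g$gene_id[1],
               cell_type = g$cell_type[1], dataset = g$dataset[1],
               best_variant = g$variant_id[b], min_fdr = g$fdr[b],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$locus_id, out$gene_id), , drop = FALSE]
}

#' Concordance between V2G-implicated genes and locus eGenes
#'
#' Reports the intersection and both directional percentages: the share of
#' eQTL eGenes evidenced by the chromatin V2G map, and the share of V2G genes
#' evidenced by the eQTL data. Because the appropriate denominator depends on
#' the question asked, both are always emitted.
#'
#' @param v2g_genes Character vector of V2G gene identifiers (restricted to
#'   the loci under comparison by the caller).
#' @param egenes Character vector of eQTL eGene identifiers (same scope).
#' @return Named list: `n_v2g`, `n_eqtl`, `n_overlap`, `pct_of_eqtl`
#'   (`100 * overlap / n_eqtl`), `pct_of_v2g` (`100 * overlap / n_v2g`).
#' @export
concordance_summary <- function(v2g_genes, egenes) {
  v <- unique(toupper(v2g_genes)); e <- unique(toupper(egenes))
  ov <- length(intersect(v, e))
  list(n_v2g = length(v), n_eqtl = length(e), n_overlap = ov,
       pct_of_eqtl = if (length(e)) 100 * ov / length(e) else NA_real_,
       pct_of_v2g = if (length(v)) 100 * ov / length(v) else NA_real_)
}
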