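# Trait-by-cell-type sharing taxonomy of variant-gene pairs, sharing
# summaries, per-group tallies, and precision-recall benchmarking.

.sharing_classes <- c("SHARED_TRAIT_SHARED_CELL", "UNIQUE_TRAIT_SHARED_CELL",
                      "SHARED_TRAIT_UNIQUE_CELL", "UNIQUE_TRAIT_UNIQUE_CELL")

.class_of <- function(multi_trait, multi_cell) {
  ifelse(multi_trait,
         ifelse(multi_cell, "SHARED_TRAIT_SHARED_CELL",
                "SHARED_TRAIT_UNIQUE_CELL"),
         ifelse(multi_cell, "UNIQUE_TRAIT_SHARED_CELL",
                "UNIQUE_TRAIT_UNIQUE_CELL"))
}

# distinct trait / cell-type counts per entity key
.axis_counts <- function(pairs, key) {
  nt <- tapply(pairs$trait, key, function(x) length(unique(x)))
  nc <- tapply(pairs$cell_type, key, function(x) length(unique(x)))
  data.frame(key = names(nt), n_traits = as.integer(nt),
             n_cell_types = as.integer(nc[names(nt)]),
             stringsAsFactors = FALSE)
}

#' Round half away from zero
#'
#' Display rounding used for printed percentages (`round()` in R rounds half
#' to even, which would print 62 for 62.5).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Classify variant-gene pairs by trait and cell-type sharing
#'
#' An entity is "shared across traits" if it occurs with >= 2 distinct traits
#' anywhere in the table, and "shared across cell types" if with >= 2
#' distinct cell types. The pair class combines both axes evaluated on the
#' (variant, gene) pair; marginal classes are also computed per variant and
#' per gene.
#'
#' @param pairs Variant-gene pair table with `trait`, `proxy`, `cell_type`,
#'   `gene_id` columns.
#' @return List of data.frames `pair` (`proxy`, `gene_id`, `n_traits`,
#'   `n_cell_types`, `class`), `variant` and `gene` (analogous marginals).
#' @export
classify_pairs <- function(pairs) {
  mk <- function(key, id_cols) {
    ax <- .axis_counts(pairs, key)
    ids <- strsplit(ax$key, "\r", fixed = TRUE)
    cols <- lapply(seq_along(id_cols), function(i) vapply(ids, `[[`, "", i))
    names(cols) <- id_cols
    out <- as.data.frame(cols, stringsAsFactors = FALSE)
    out$n_traits <- ax$n_traits
    out$n_cell_types <- ax$n_cell_types
    out$class <- .class_of(ax$n_traits >= 2, ax$n_cell_types >= 2)
    out
  }
  list(pair = mk(paste(pairs$proxy, pairs$gene_id, sep = "\r"),
                 c("proxy", "gene_id")),
       variant = mk(pairs$proxy, "proxy"),
       gene = mk(pairs$gene_id, "gene_id"))
}

#' Summarize sharing of variants and genes across traits and cell types
#'
#' Percentages are `100 * (entities seen with >= 2 traits or cell types) /
#' (total entities)`; full precision is kept in the `pct_*` fields and
#' half-away-from-zero integer rounding is applied in the `display` field.
#'
#' @param pairs Variant-gene pair table.
#' @return Object of class `sharing_summary`: list with counts
#'   (`n_variants`, `n_genes`, `n_pairs`, `n_pairs_unique_both`), raw
#'   percentages (`pct_variants_multi_trait`, `pct_variants_multi_cell`,
#'   `pct_genes_multi_trait`, `pct_genes_multi_cell`) and `display`
#'   (integer-rounded percentages).
#' @export
summarize_sharing <- function(pairs) {
  if (!nrow(pairs)) stop("empty pair table")
  cl <- classify_pairs(pairs)
  v <- cl$variant; g <- cl$gene; p <- cl$pair
  pct <- function(k, n) 100 * k / n
  res <- list(
    n_variants = nrow(v), n_genes = nrow(g), n_pairs = nrow(p),
    n_pairs_unique_both = sum(p$class == "UNIQUE_TRAIT_UNIQUE_CELL"),
    pct_variants_multi_trait = pct(sum(v$n_traits >= 2), nrow(v)),
    pct_variants_multi_cell = pct(sum(v$n_cell_types >= 2), nrow(v)),
    pct_genes_multi_trait = pct(sum(g$n_traits >= 2), nrow(g)),
    pct_genes_multi_cell = pct(sum(g$n_cell_types >= 2), nrow(g)))
  res$display <- vapply(res[grep("^pct_", names(res))],
                        round_half_away, numeric(1))
  class(res) <- "sharing_summary"
  res
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf("Variant-gene sharing: %d variants, %d genes, %d pairs\n",
              x$n_variants, x$n_genes, x$n_pairs))
  cat(sprintf("  variants multi-trait: %d%%  multi-cell: %d%%\n",
              x$display[["pct_variants_multi_trait"]],
              x$display[["pct_variants_multi_cell"]]))
  cat(sprintf("  genes    multi-trait: %d%%  multi-cell: %d%%\n",
              x$display[["pct_genes_multi_trait"]],
              x$display[["pct_genes_multi_cell"]]))
  cat(sprintf("  pairs unique to both trait and cell type: %d\n",
              x$n_pairs_unique_both))
  invisible(x)
}

#' Per-trait or per-cell-type tallies of variants and genes
#'
#' A group-exclusive gene appears for exactly one group on the chosen axis.
#' Output is sorted descending by exclusive-gene count.
#'
#' @param pairs Variant-gene pair table.
#' @param axis `"trait"` or `"cell_type"`.
#' @return data.frame with `group`, `n_variants`, `n_genes`,
#'   `n_exclusive_genes`.
#' @export
tally_by_group <- function(pairs, axis = c("trait", "cell_type")) {
  axis <- match.arg(axis)
  grp <- pairs[[axis]]
  gene_groups <- tapply(grp, pairs$gene_id,
                        function(x) length(unique(x)))
  exclusive <- names(gene_groups)[gene_groups == 1]
  groups <- sort(unique(grp))
  rows <- lapply(groups, function(g) {
    sel <- grp == g
    data.frame(group = g,
               n_variants = length(unique(pairs$proxy[sel])),
               n_genes = length(unique(pairs$gene_id[sel])),
               n_exclusive_genes = length(unique(
                 pairs$gene_id[sel][pairs$gene_id[sel] %in% exclusive])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_exclusive_genes, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precision and recall of a predicted gene set against a truth set
#'
#' Precision is the fraction of predicted genes in the truth set; recall is
#' the fraction of truth-set genes predicted. Identifiers are compared after
#' upper-casing and optional alias mapping.
#'
#' @param predicted Character vector of predicted gene identifiers
#'   (non-empty).
#' @param truth Character vector of truth-set genes (non-empty).
#' @param aliases Optional named character vector mapping alias -> canonical
#'   symbol, applied to both sets.
#' @return Named list `precision`, `recall`, `n_overlap`.
#' @export
precision_recall <- function(predicted, truth, aliases = NULL) {
  norm <- function(x) {
    x <- toupper(unique(x))
    if (!is.null(aliases)) {
      al <- stats::setNames(toupper(aliases), toupper(names(aliases)))
      hit <- x %in% names(al)
      x[hit] <- unname(al[x[hit]])
      x <- unique(x)
    }
    x
  }
  p <- norm(predicted); t <- norm(truth)
  if (!length(p)) stop("empty predicted gene set")
  if (!length(t)) stop("empty truth gene set")
  ov <- length(intersect(p, t))
  list(precision = ov / length(p), recall = ov / length(t), n_overlap = ov)
}
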