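# Seeded synthetic-data generator with planted ground truth.
#
# Features are laid out on a lattice of disjoint 2.5 kb slots so that no two
# entities overlap unless the generator planted the overlap. Each gene,
# distal OCR, negative loop anchor and free-standing variant owns a slot;
# promoter OCRs live inside their gene's promoter window; planted loops
# connect a distal OCR's interval to a target promoter window. Under this
# construction the cRE caller and the V2G mapper recover the planted truth
# exactly, which is what the noiseless end-to-end checks assert.

.SLOT_W <- 2500L

#' Configuration for the synthetic dataset
#'
#' Defaults define the study conditions used throughout the test-suite: a
#' two-chromosome 10 Mb-per-chromosome genome, 300 genes, 4 cell types with
#' ~2,000 peaks each of which 15% loop to a promoter, 3 traits with 20
#' sentinels each and 5-30 proxies per sentinel straddling the r2 = 0.8
#' threshold, and eQTL loci of 200 SNPs with an AR(1) LD structure and a
#' causal |z| of 8 at n = 10,000 per study.
#'
#' @param seed Integer RNG seed.
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes,n_cell_types,n_ocr_per_cell,frac_ocr_looped Regulatory
#'   landscape shape; `frac_ocr_looped` is the fraction of a cell type's
#'   peaks planted as promoter-contacting.
#' @param n_traits,n_sentinels_per_trait,proxies_per_sentinel GWAS shape
#'   (`proxies_per_sentinel` is an inclusive range).
#' @param frac_causal_proxies_in_cre Probability a proxy is placed inside a
#'   planted cRE.
#' @param frac_multi_trait_variants Fraction of in-cRE proxies replicated
#'   into a second trait.
#' @param frac_multi_cell_contacts Probability a planted contact is
#'   replicated across >= 2 cell types.
#' @param eqtl List: `n_snps`, `n_gwas`, `n_eqtl`, `causal_z`, `ld_rho`,
#'   `frac_h4`, `frac_h3`.
#' @param mhc_mimic Optional masked interval (list/data.frame with `chrom`,
#'   `start`, `end`); one sentinel block is planted inside it and excluded
#'   from the ground truth.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 42, n_chroms = 2, chrom_length = 1e7,
                       n_genes = 300, n_cell_types = 4, n_ocr_per_cell = 2000,
                       frac_ocr_looped = 0.15, n_traits = 3,
                       n_sentinels_per_trait = 20,
                       proxies_per_sentinel = c(5, 30),
                       frac_causal_proxies_in_cre = 0.3,
                       frac_multi_trait_variants = 0.2,
                       frac_multi_cell_contacts = 0.5,
                       eqtl = list(n_snps = 200, n_gwas = 10000,
                                   n_eqtl = 10000, causal_z = 8,
                                   ld_rho = 0.95, frac_h4 = 0.4,
                                   frac_h3 = 0.4),
                       mhc_mimic = NULL) {
  cfg <- as.list(environment())
  stopifnot(n_chroms > 0, chrom_length > 0, n_genes > 0, n_cell_types > 0,
            n_ocr_per_cell > 0, n_traits > 0, n_sentinels_per_trait > 0,
            length(proxies_per_sentinel) == 2,
            proxies_per_sentinel[1] >= 1,
            frac_ocr_looped >= 0, frac_ocr_looped <= 1,
            frac_causal_proxies_in_cre >= 0,
            frac_causal_proxies_in_cre <= 1)
  structure(cfg, class = "sim_config")
}

.set_sim_seed <- function(seed, stream = 0L) {
  set.seed(seed + stream, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Simulate a genome: genes, per-cell-type peaks and loops, planted cREs
#'
#' @param config A [sim_config()].
#' @return List with `config`, `chrom_sizes`, `genes`, `promoters`, `ocrs`,
#'   `loops` (all cell types concatenated), and `truth` (list with
#'   `contacts` — the planted (cell type, cRE, gene, loop) table —,
#'   `contact_ocrs`, and `variant_slots` reserved for GWAS placement).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .set_sim_seed(config$seed, 0L)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  sizes <- stats::setNames(rep(as.integer(config$chrom_length),
                               config$n_chroms), chroms)
  n_slot_chrom <- as.integer(config$chrom_length) %/% .SLOT_W
  slots <- data.frame(chrom = rep(chroms, each = n_slot_chrom),
                      base = rep((seq_len(n_slot_chrom) - 1L) * .SLOT_W,
                                 times = config$n_chroms),
                      stringsAsFactors = FALSE)
  slots <- slots[sample(nrow(slots)), , drop = FALSE]

  n_master <- ceiling(config$n_ocr_per_cell * 1.3)
  n_neg_anchor <- 400L
  n_var <- config$n_traits * config$n_sentinels_per_trait *
    config$proxies_per_sentinel[2]
  need <- config$n_genes + n_master + n_neg_anchor + n_var
  if (need > nrow(slots))
    stop("infeasible density: ", need, " slots needed, ",
         nrow(slots), " available; enlarge the genome")
  cursor <- 0L
  take <- function(n) {
    out <- slots[cursor + seq_len(n), , drop = FALSE]
    cursor <<- cursor + n
    rownames(out) <- NULL
    out
  }
  gene_slots <- take(config$n_genes)
  distal_slots <- take(n_master)
  neg_slots <- take(n_neg_anchor)
  var_slots <- take(n_var)

  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  tss <- ifelse(strand == "+", gene_slots$base + 1601L,
                gene_slots$base + 601L)
  genes <- data.frame(gene_id = sprintf("GENE%04d", seq_len(config$n_genes)),
                      gene_name = sprintf("Gene%04d", seq_len(config$n_genes)),
                      chrom = gene_slots$chrom, tss = as.integer(tss),
                      strand = strand, stringsAsFactors = FALSE)
  promoters <- make_promoters(genes, chrom_sizes = sizes)
  # promoter-internal OCR coordinates per gene (used where a promoter is open)
  tss0 <- genes$tss - 1L
  pocr <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                     start = tss0 - 200L, end = tss0 + 200L,
                     peak_id = paste0("pocr_", genes$gene_id),
                     stringsAsFactors = FALSE)

  width <- sample(300:700, n_master, replace = TRUE)
  master <- data.frame(peak_id = sprintf("ocr_%05d", seq_len(n_master)),
                       chrom = distal_slots$chrom,
                       start = distal_slots$base + 900L,
                       stringsAsFactors = FALSE)
  master$end <- master$start + width

  cells <- sprintf("cell%02d", seq_len(config$n_cell_types))
  n_contact <- round(config$frac_ocr_looped * config$n_ocr_per_cell)
  contact_idx <- sample(n_master, n_contact)
  contacts <- list()
  for (ci in contact_idx) {
    chrom <- master$chrom[ci]
    cand <- which(genes$chrom == chrom)
    ng <- sample(1:3, 1, prob = c(0.5, 0.3, 0.2))
    gsel <- sample(cand, min(ng, length(cand)))
    cl <- if (stats::runif(1) < config$frac_multi_cell_contacts &&
              config$n_cell_types >= 2)
      sample(cells, sample(2:config$n_cell_types, 1))
    else sample(cells, 1)
    for (g in gsel) for (ct in cl)
      contacts[[length(contacts) + 1]] <-
        data.frame(cell_type = ct, peak_id = master$peak_id[ci],
                   gene_id = genes$gene_id[g], stringsAsFactors = FALSE)
  }
  contacts <- if (length(contacts)) do.call(rbind, contacts)
              else data.frame(cell_type = character(),
                              peak_id = character(),
                              gene_id = character(),
                              stringsAsFactors = FALSE)
  contacts$loop_id <- character(nrow(contacts))

  # per-cell random openness of promoters and presence of distal peaks
  open_prom <- matrix(stats::runif(config$n_genes * config$n_cell_types) < 0.6,
                      nrow = config$n_genes,
                      dimnames = list(genes$gene_id, cells))
  for (i in seq_len(nrow(contacts)))    # contacted promoters must be open
    open_prom[contacts$gene_id[i], contacts$cell_type[i]] <- TRUE

  ocr_list <- list(); loop_list <- list()
  neg_by_chrom <- split(neg_slots, neg_slots$chrom)
  for (ct in cells) {
    forced <- unique(contacts$peak_id[contacts$cell_type == ct])
    open_g <- rownames(open_prom)[open_prom[, ct]]
    prows <- pocr[pocr$gene_id %in% open_g, , drop = FALSE]
    n_prom_ocr <- nrow(prows)
    n_extra <- config$n_ocr_per_cell - n_prom_ocr - length(forced)
    if (n_extra < 0)
      stop("infeasible config: forced peaks exceed n_ocr_per_cell")
    pool <- setdiff(master$peak_id, forced)
    extra <- sample(pool, min(n_extra, length(pool)))
    sel <- master[master$peak_id %in% c(forced, extra), , drop = FALSE]
    jitter_ok <- !(sel$peak_id %in% forced)
    jit <- integer(nrow(sel))
    jit[jitter_ok] <- sample(-50:50, sum(jitter_ok), replace = TRUE)
    ocr_ct <- data.frame(chrom = c(sel$chrom, prows$chrom),
                         start = c(sel$start + jit, prows$start),
                         end = c(sel$end + jit, prows$end),
                         peak_id = c(sel$peak_id, prows$peak_id),
                         cell_type = ct, stringsAsFactors = FALSE)
    ocr_list[[ct]] <- ocr_ct[order(ocr_ct$chrom, ocr_ct$start), ,
                             drop = FALSE]

    cc <- contacts[contacts$cell_type == ct, , drop = FALSE]
    planted <- NULL
    if (nrow(cc)) {
      mi <- match(cc$peak_id, master$peak_id)
      pi <- match(cc$gene_id, promoters$gene_id)
      planted <- data.frame(chrom = master$chrom[mi],
                            start1 = master$start[mi], end1 = master$end[mi],
                            start2 = promoters$start[pi],
                            end2 = promoters$end[pi],
                            stringsAsFactors = FALSE)
    }
    negs <- do.call(rbind, lapply(neg_by_chrom, function(ns) {
      if (nrow(ns) < 2) return(NULL)
      k <- nrow(ns) %/% 2
      data.frame(chrom = ns$chrom[1],
                 start1 = ns$base[seq_len(k) * 2 - 1] + 500L,
                 end1 = ns$base[seq_len(k) * 2 - 1] + 1500L,
                 start2 = ns$base[seq_len(k) * 2] + 500L,
                 end2 = ns$base[seq_len(k) * 2] + 1500L,
                 stringsAsFactors = FALSE)
    }))
    lp <- rbind(planted, negs)
    lp$cell_type <- ct
    lp$source <- "pcc"
    lp$score <- round(stats::runif(nrow(lp), 5, 15), 2)
    lp$loop_id <- sprintf("%s_pcc_L%d", ct, seq_len(nrow(lp)))
    loop_list[[ct]] <- lp[, c("loop_id", "cell_type", "source", "chrom",
                              "start1", "end1", "start2", "end2", "score")]
    if (nrow(cc))   # planted loops lead lp in cc row order
      contacts$loop_id[contacts$cell_type == ct] <-
        lp$loop_id[seq_len(nrow(cc))]
  }
  ocrs <- do.call(rbind, ocr_list)
  loops <- do.call(rbind, loop_list)
  rownames(ocrs) <- rownames(loops) <- NULL

  contact_ocrs <- master[master$peak_id %in% contacts$peak_id, , drop = FALSE]
  rownames(contact_ocrs) <- NULL
  list(config = config, chrom_sizes = sizes, genes = genes,
       promoters = promoters, ocrs = ocrs, loops = loops,
       truth = list(contacts = contacts, contact_ocrs = contact_ocrs,
                    variant_slots = var_slots))
}

#' Simulate GWAS sentinels, LD-proxy blocks, and the planted V2G pair table
#'
#' Sentinels get proxy blocks whose r-squared values straddle the 0.8
#' threshold (sub-threshold proxies are negative controls); a configured
#' fraction of proxies land inside planted cREs, a fraction of those are
#' replicated into a second trait, and every sentinel appears as its own
#' proxy with r2 = 1. The returned `truth_pairs` table is the exact set of
#' variant-gene pairs the V2G pipeline should recover.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @return List with `sentinels`, `proxies`, `ld_r2` (pairwise sentinel LD
#'   matrix), `truth_pairs`, and `sumstats` (minimal per-trait summary
#'   statistics for the proxies).
#' @export
simulate_gwas <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  .set_sim_seed(config$seed, 1L)
  traits <- sprintf("trait_%s", LETTERS[seq_len(config$n_traits)])
  contacts <- genome$truth$contacts
  cocr <- genome$truth$contact_ocrs
  vslots <- genome$truth$variant_slots
  vused <- logical(nrow(vslots))
  next_slot <- function(chrom) {
    i <- which(vslots$chrom == chrom & !vused)[1]
    if (is.na(i)) stop("variant slots exhausted on ", chrom)
    vused[i] <<- TRUE
    vslots$base[i] + 1200L
  }

  rs <- 0L
  new_id <- function() {
    rs <<- rs + 1L
    sprintf("rs%06d", rs)
  }
  mhc <- config$mhc_mimic
  sent_rows <- list(); prox_rows <- list()
  for (ti in seq_along(traits)) {
    for (si in seq_len(config$n_sentinels_per_trait)) {
      in_mhc_block <- !is.null(mhc) && ti == 1 && si == 1
      chrom <- if (in_mhc_block) as.character(mhc$chrom)
               else sample(names(genome$chrom_sizes), 1)
      k <- sample(config$proxies_per_sentinel[1]:
                    config$proxies_per_sentinel[2], 1)
      sid <- new_id()
      ids <- c(sid, vapply(seq_len(k - 1), function(i) new_id(), ""))
      r2 <- c(1, ifelse(stats::runif(k - 1) < 0.7,
                        stats::runif(k - 1, 0.8, 1),
                        stats::runif(k - 1, 0.2, 0.8 - 1e-6)))
      chrom_cocr <- cocr[cocr$chrom == chrom, , drop = FALSE]
      pos <- integer(k)
      in_cre <- logical(k)
      for (i in seq_len(k)) {
        if (in_mhc_block) {
          pos[i] <- as.integer(mhc$start) + 100L * i
        } else if (nrow(chrom_cocr) &&
                   stats::runif(1) < config$frac_causal_proxies_in_cre) {
          o <- chrom_cocr[sample(nrow(chrom_cocr), 1), ]
          pos[i] <- as.integer(o$start + (o$end - o$start) %/% 2)
          in_cre[i] <- TRUE
        } else {
          pos[i] <- next_slot(chrom)
        }
      }
      sent_rows[[length(sent_rows) + 1]] <-
        data.frame(trait = traits[ti], variant_id = sid, chrom = chrom,
                   pos = pos[1], stringsAsFactors = FALSE)
      prox_rows[[length(prox_rows) + 1]] <-
        data.frame(trait = traits[ti], sentinel = sid, proxy = ids,
                   chrom = chrom, pos = pos, r2 = r2, in_cre = in_cre,
                   stringsAsFactors = FALSE)
    }
  }
  sentinels <- do.call(rbind, sent_rows)
  proxies <- do.call(rbind, prox_rows)
  rownames(sentinels) <- rownames(proxies) <- NULL

  # multi-trait sharing: replicate the configured fraction of distinct
  # in-cRE high-LD proxies into a second trait, attached to a
  # same-chromosome sentinel; the planted multi-trait variant fraction of
  # the pair table equals this fraction up to the rounding of n_share
  if (config$n_traits >= 2 && config$frac_multi_trait_variants > 0) {
    elig <- proxies[proxies$r2 >= 0.8 & proxies$in_cre, , drop = FALSE]
    elig <- elig[!duplicated(elig$proxy), , drop = FALSE]
    n_share <- round(config$frac_multi_trait_variants * nrow(elig))
    if (n_share > 0) {
      shared <- elig[sample(nrow(elig), n_share), , drop = FALSE]
      add <- list()
      for (i in seq_len(nrow(shared))) {
        cand <- sentinels[sentinels$trait != shared$trait[i] &
                            sentinels$chrom == shared$chrom[i], ,
                          drop = FALSE]
        if (!nrow(cand)) next
        host <- cand[sample(nrow(cand), 1), ]
        add[[length(add) + 1]] <-
          data.frame(trait = host$trait, sentinel = host$variant_id,
                     proxy = shared$proxy[i], chrom = shared$chrom[i],
                     pos = shared$pos[i],
                     r2 = round(stats::runif(1, 0.8, 1), 3),
                     in_cre = TRUE, stringsAsFactors = FALSE)
      }
      if (length(add)) proxies <- rbind(proxies, do.call(rbind, add))
    }
  }
  proxies$in_cre <- NULL
  rownames(proxies) <- NULL

  # pairwise sentinel LD: low by default, high for sentinels sharing a proxy
  ids <- sentinels$variant_id
  ld <- matrix(round(stats::runif(length(ids)^2, 0, 0.5), 3),
               nrow = length(ids), dimnames = list(ids, ids))
  ld[lower.tri(ld)] <- t(ld)[lower.tri(ld)]
  diag(ld) <- 1
  by_proxy <- split(proxies$sentinel, proxies$proxy)
  for (ss in by_proxy) {
    ss <- unique(ss)
    if (length(ss) >= 2)
      for (a in seq_along(ss)) for (b in seq_along(ss))
        if (a < b) {
          r <- round(stats::runif(1, 0.85, 1), 3)
          ld[ss[a], ss[b]] <- r
          ld[ss[b], ss[a]] <- r
        }
  }

  truth_pairs <- .planted_pairs(proxies, genome, mhc)

  sumstats <- lapply(stats::setNames(traits, traits), function(tr) {
    pp <- proxies[proxies$trait == tr, , drop = FALSE]
    z <- ifelse(pp$r2 >= 0.8, stats::runif(nrow(pp), 6, 10),
                stats::rnorm(nrow(pp)))
    se <- 0.02
    data.frame(variant = pp$proxy, chrom = pp$chrom, pos = pp$pos,
               effect_allele = "A", other_allele = "G",
               beta = round(z * se, 6), se = se,
               pvalue = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  list(sentinels = sentinels, proxies = proxies, ld_r2 = ld,
       truth_pairs = truth_pairs, sumstats = sumstats)
}

# ground-truth pair table implied by the planted contacts; excludes
# sub-threshold proxies and anything inside the masked interval
.planted_pairs <- function(proxies, genome, mhc = NULL) {
  contacts <- genome$truth$contacts
  cocr <- genome$truth$contact_ocrs
  keep <- proxies$r2 >= 0.8
  if (!is.null(mhc))
    keep <- keep & !(proxies$chrom == as.character(mhc$chrom) &
                       proxies$pos >= mhc$start & proxies$pos < mhc$end)
  pp <- proxies[keep, , drop = FALSE]
  if (!nrow(pp) || !nrow(cocr))
    return(data.frame(trait = character(), sentinel = character(),
                      proxy = character(), cell_type = character(),
                      cre_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  rows <- list()
  for (i in seq_len(nrow(pp))) {
    hit <- cocr[cocr$chrom == pp$chrom[i] & cocr$start <= pp$pos[i] &
                  pp$pos[i] < cocr$end, , drop = FALSE]
    if (!nrow(hit)) next
    cc <- contacts[contacts$peak_id %in% hit$peak_id, , drop = FALSE]
    if (!nrow(cc)) next
    rows[[length(rows) + 1]] <-
      data.frame(trait = pp$trait[i], sentinel = pp$sentinel[i],
                 proxy = pp$proxy[i], cell_type = cc$cell_type,
                 cre_id = cc$peak_id, gene_id = cc$gene_id,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(trait = character(), sentinel = character(),
                      proxy = character(), cell_type = character(),
                      cre_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$trait, out$proxy, out$cell_type, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate paired GWAS/eQTL locus summary statistics for colocalization
#'
#' Each locus holds `m` SNPs with an AR(1) LD structure
#' (\eqn{corr = \rho^{|i-j|}}); marginal z-scores are the LD-weighted causal
#' signal plus unit noise, \eqn{\beta = z/\sqrt n}, \eqn{SE = 1/\sqrt n}.
#' `H4` loci share one causal SNP between trait and eQTL; `H3` loci use two
#' causal SNPs in low LD (quarter points of the block); `H0` loci have no
#' causal signal. The noise term is drawn from MVN(0, C): under the
#' single-causal model the marginal z-scores are themselves correlated by
#' LD, which is what keeps shared- and distinct-causal configurations
#' separable.
#'
#' @param config A [sim_config()].
#' @param loci Optional locus table (its `locus_id`s are reused); otherwise
#'   `n_loci` synthetic locus labels are created.
#' @param n_loci Number of loci when `loci` is `NULL`.
#' @return List of per-locus lists: `locus_id`, `label` (`"H4"`, `"H3"`,
#'   `"H0"`), `gwas` and `eqtl` data.frames (`variant_id`, `beta`, `se`,
#'   `pvalue`, `maf`, `n`, and `gene_id` on the eQTL side).
#' @export
simulate_eqtl <- function(config, loci = NULL, n_loci = 20) {
  stopifnot(inherits(config, "sim_config"))
  .set_sim_seed(config$seed, 2L)
  e <- config$eqtl
  m <- e$n_snps
  if (m < 2) stop("need >= 2 SNPs per locus")
  ids <- if (!is.null(loci)) loci$locus_id else sprintf("locus_%03d",
                                                        seq_len(n_loci))
  nl <- length(ids)
  labels <- sample(c(rep("H4", round(e$frac_h4 * nl)),
                     rep("H3", round(e$frac_h3 * nl)),
                     rep("H0", nl - round(e$frac_h4 * nl) -
                           round(e$frac_h3 * nl))))
  C <- e$ld_rho^abs(outer(seq_len(m), seq_len(m), "-"))
  R <- chol(C)                       # C = R'R, for LD-correlated noise
  out <- vector("list", nl)
  for (i in seq_len(nl)) {
    vid <- sprintf("%s_snp%04d", ids[i], seq_len(m))
    lab <- labels[i]
    if (lab == "H4") {
      c1 <- c2 <- sample(m, 1)
    } else if (lab == "H3") {
      c1 <- max(1L, round(m / 4)); c2 <- min(m, round(3 * m / 4))
    } else c1 <- c2 <- NA_integer_
    z1 <- drop(crossprod(R, stats::rnorm(m)))
    z2 <- drop(crossprod(R, stats::rnorm(m)))
    if (!is.na(c1)) z1 <- z1 + C[, c1] * e$causal_z
    if (!is.na(c2)) z2 <- z2 + C[, c2] * e$causal_z
    maf <- round(stats::runif(m, 0.05, 0.5), 4)
    mk <- function(z, n, gene = NULL) {
      df <- data.frame(variant_id = vid, beta = z / sqrt(n),
                       se = 1 / sqrt(n), pvalue = 2 * stats::pnorm(-abs(z)),
                       maf = maf, n = n, stringsAsFactors = FALSE)
      if (!is.null(gene)) df$gene_id <- gene
      df
    }
    out[[i]] <- list(locus_id = ids[i], label = lab,
                     gwas = mk(z1, e$n_gwas),
                     eqtl = mk(z2, e$n_eqtl,
                               gene = sprintf("EGENE_%s", ids[i])))
  }
  out
}
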