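# End-to-end orchestration of the synthetic-data pipeline: every stage
# behind one call, with a JSON run manifest recording parameters, outputs
# and checksums so identical inputs reproduce identical outputs.

.STAGES <- c("cre", "annot", "v2g", "sharing", "benchmark", "loci",
             "coloc", "motif")

.stage_deps <- list(cre = character(), annot = "cre", v2g = "cre",
                    sharing = "v2g", benchmark = "v2g", loci = character(),
                    coloc = "loci", motif = character())

.stage_outputs <- list(cre = "cres.tsv", annot = "annot_CRE.annot",
                       v2g = "pairs.tsv", sharing = "sharing_summary.tsv",
                       benchmark = "benchmark.tsv", loci = "loci.tsv",
                       coloc = "coloc.tsv", motif = "motif_hits.tsv")

.write_stage_tsv <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the variant-to-gene pipeline on a synthetic dataset
#'
#' Simulates the genome/GWAS inputs under the configured seed, then executes
#' the requested stages in dependency order: `cre` (cRE definition per cell
#' type), `annot` (annotation partition + LDSC-format export), `v2g`
#' (proxy filtering and variant-gene mapping), `sharing` (sharing taxonomy
#' summary), `benchmark` (precision-recall against the planted truth genes),
#' `loci` (LD-merged locus construction), `coloc` (ABF colocalization on
#' simulated locus stats), `motif` (disruption scan on a planted PWM
#' fixture). A stage whose prerequisite output is neither requested nor
#' already present in `out_dir` raises a dependency error naming the stage.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @param stages Subset of the eight stage names; default all.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`): stages run, parameters, per-file md5 checksums,
#'   package version.
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         stages = .STAGES) {
  stopifnot(inherits(config, "sim_config"))
  bad <- setdiff(stages, .STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- .STAGES[.STAGES %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (st in stages) {
    for (dep in .stage_deps[[st]]) {
      if (!(dep %in% stages) &&
          !file.exists(file.path(out_dir, .stage_outputs[[dep]])))
        stop("dependency error: stage '", st, "' requires output of '",
             dep, "' which is neither requested nor present")
    }
  }

  genome <- simulate_genome(config)
  gwas <- simulate_gwas(config, genome)
  cells <- unique(genome$ocrs$cell_type)

  env <- new.env(parent = emptyenv())
  load_cres <- function() {
    if (!is.null(env$cres)) return(env$cres)
    env$cres <- utils::read.table(file.path(out_dir, "cres.tsv"),
                                  header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
    env$cres
  }
  load_pairs <- function() {
    if (!is.null(env$pairs)) return(env$pairs)
    env$pairs <- utils::read.table(file.path(out_dir, "pairs.tsv"),
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
    env$pairs
  }
  files <- character()
  add <- function(p) files <<- c(files, p)

  for (st in stages) {
    if (st == "cre") {
      cres <- do.call(rbind, lapply(cells, function(ct) {
        define_cres(genome$ocrs[genome$ocrs$cell_type == ct, ],
                    genome$loops[genome$loops$cell_type == ct, ],
                    genome$promoters)
      }))
      env$cres <- cres
      add(.write_stage_tsv(cres, out_dir, "cres.tsv"))
      bed <- unique(cres[, c("chrom", "start", "end", "cre_id")])
      names(bed)[4] <- "peak_id"
      add(write_bed(bed, file.path(out_dir, "cres.bed")))
    } else if (st == "annot") {
      cres <- load_cres()
      ct <- cells[1]
      part <- partition_annotations(
        genome$ocrs[genome$ocrs$cell_type == ct, ],
        cres[cres$cell_type == ct, ], genome$promoters)
      tmpl <- gwas$proxies[order(gwas$proxies$chrom, gwas$proxies$pos), ]
      tmpl <- tmpl[!duplicated(tmpl$proxy), ]
      template <- data.frame(chrom = tmpl$chrom, bp = tmpl$pos,
                             snp = tmpl$proxy, cm = 0)
      template <- template[order(template$chrom, template$bp), ]
      ann <- export_ldsc_annot(part, template, "CRE",
                               file.path(out_dir, "annot_CRE.annot"))
      add(file.path(out_dir, "annot_CRE.annot"))
    } else if (st == "v2g") {
      cres <- load_cres()
      filt <- filter_proxies(gwas$proxies, gwas$sentinels,
                             mhc = if (!is.null(config$mhc_mimic))
                               as.data.frame(config$mhc_mimic)
                             else .default_mhc())
      pairs <- map_variants_to_genes(filt, cres)
      env$pairs <- pairs
      add(.write_stage_tsv(pairs, out_dir, "pairs.tsv"))
    } else if (st == "sharing") {
      pairs <- load_pairs()
      s <- summarize_sharing(pairs)
      sdf <- data.frame(metric = c("n_variants", "n_genes", "n_pairs",
                                   "n_pairs_unique_both",
                                   names(s$display)),
                        value = c(s$n_variants, s$n_genes, s$n_pairs,
                                  s$n_pairs_unique_both, s$display))
      add(.write_stage_tsv(sdf, out_dir, "sharing_summary.tsv"))
      add(.write_stage_tsv(tally_by_group(pairs, "trait"), out_dir,
                           "tally_trait.tsv"))
      add(.write_stage_tsv(tally_by_group(pairs, "cell_type"), out_dir,
                           "tally_cell_type.tsv"))
    } else if (st == "benchmark") {
      pairs <- load_pairs()
      truth_genes <- unique(gwas$truth_pairs$gene_id)
      pr <- precision_recall(unique(pairs$gene_id), truth_genes)
      add(.write_stage_tsv(
        data.frame(precision = pr$precision, recall = pr$recall,
                   n_overlap = pr$n_overlap), out_dir, "benchmark.tsv"))
    } else if (st == "loci") {
      filt <- filter_proxies(gwas$proxies, gwas$sentinels,
                             mhc = if (!is.null(config$mhc_mimic))
                               as.data.frame(config$mhc_mimic)
                             else .default_mhc())
      sent <- gwas$sentinels[gwas$sentinels$variant_id %in% filt$sentinel, ]
      loci <- build_loci(sent, filt, ld_r2 = gwas$ld_r2)
      env$loci <- loci
      add(.write_stage_tsv(loci, out_dir, "loci.tsv"))
    } else if (st == "coloc") {
      loci <- env$loci
      if (is.null(loci))
        loci <- utils::read.table(file.path(out_dir, "loci.tsv"),
                                  header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
      sims <- simulate_eqtl(config, loci = loci)
      res <- do.call(rbind, lapply(sims, function(s) {
        r <- coloc_abf(s$gwas, s$eqtl, trait_type = "cc",
                       eqtl_type = "quant")
        top <- r$per_snp[which.max(r$per_snp$snp_pp_h4), ]
        data.frame(locus_id = s$locus_id, gene_id = s$eqtl$gene_id[1],
                   label = s$label, nsnps = r$nsnps,
                   t(r$summary), top_snp = top$variant_id,
                   top_snp_pp_h4 = top$snp_pp_h4,
                   stringsAsFactors = FALSE)
      }))
      add(.write_stage_tsv(res, out_dir, "coloc.tsv"))
    } else if (st == "motif") {
      counts <- matrix(c(90, 4, 3, 3,
                         2, 92, 3, 3,
                         3, 3, 91, 3,
                         88, 4, 4, 4,
                         3, 3, 3, 91,
                         4, 90, 3, 3), ncol = 4, byrow = TRUE)
      pwm <- make_pwm(counts, tf_name = "SYN_TF1")
      ref <- paste0("ACGT", pwm_consensus(pwm), "ACGT")
      alt <- ref
      pos <- 4 + 3          # third motif column (consensus G)
      substr(alt, pos, pos) <- "T"
      hits <- scan_variant(pwm, ref, alt, variant_id = "rs_synthetic_1")
      add(.write_stage_tsv(hits, out_dir, "motif_hits.tsv"))
    }
  }

  manifest <- list(
    package = "chromV2G",
    version = as.character(utils::packageVersion("chromV2G")),
    seed = config$seed,
    stages = stages,
    parameters = config[!vapply(config, is.null, logical(1))],
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}
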