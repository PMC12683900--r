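# Fixture geometry (chr1): promoter of G1 at [1000,3000) around TSS 2501(+),
# promoter of G2 at [8499,10499) around TSS 10000(+); OCRs and loops placed
# relative to these.

.cre_fixture <- function() {
  sizes <- c(chr1 = 1e6)
  genes <- toy_genes("chr1", c(2501, 10000), ids = c("G1", "G2"))
  promoters <- make_promoters(genes, chrom_sizes = sizes)
  list(sizes = sizes, genes = genes, promoters = promoters)
}

test_that("an OCR looped to an open promoter is a cRE; unlooped is not", {
  fx <- .cre_fixture()
  ocrs <- toy_ocrs("chr1", c(50000, 70000, 1500), c(50500, 70500, 1900),
                   ids = c("A", "B", "promOCR_G1"))
  loops <- toy_loops("chr1", 49900, 50400, 1200, 2000)  # A <-> G1 promoter
  cres <- define_cres(ocrs, loops, fx$promoters)
  expect_equal(nrow(cres), 1)
  expect_equal(cres$cre_id, "A")
  expect_equal(cres$gene_id, "G1")
  expect_false("B" %in% cres$cre_id)
})

test_that("require_open_promoter gates contacts on promoter accessibility", {
  fx <- .cre_fixture()
  ocrs <- toy_ocrs("chr1", 50000, 50500, ids = "A")  # no OCR in G1 promoter
  loops <- toy_loops("chr1", 49900, 50400, 1200, 2000)
  expect_equal(nrow(define_cres(ocrs, loops, fx$promoters)), 0)
  open <- define_cres(ocrs, loops, fx$promoters,
                      require_open_promoter = FALSE)
  expect_equal(open$gene_id, "G1")
})

test_that("multiple loops to different promoters accumulate contacted genes", {
  fx <- .cre_fixture()
  ocrs <- toy_ocrs("chr1", c(50000, 1500, 8600), c(50500, 1900, 9000),
                   ids = c("A", "pG1", "pG2"))
  loops <- toy_loops("chr1",
                     s1 = c(49900, 50100), e1 = c(50400, 50600),
                     s2 = c(1200, 8499), e2 = c(2000, 9000))
  cres <- define_cres(ocrs, loops, fx$promoters)
  a <- cres[cres$cre_id == "A", ]
  expect_setequal(a$gene_id, c("G1", "G2"))
  expect_equal(sum(a$n_loops), 2)
  # brute-force check of every (ocr, loop, promoter) combination
  expected <- 0
  for (o in seq_len(nrow(ocrs))) for (l in seq_len(nrow(loops))) {
    o1 <- brute_overlap("chr1", ocrs$start[o], ocrs$end[o], "chr1",
                        loops$start1[l], loops$end1[l])
    o2 <- brute_overlap("chr1", ocrs$start[o], ocrs$end[o], "chr1",
                        loops$start2[l], loops$end2[l])
    for (p in seq_len(nrow(fx$promoters))) {
      p1 <- brute_overlap("chr1", fx$promoters$start[p],
                          fx$promoters$end[p], "chr1",
                          loops$start1[l], loops$end1[l])
      p2 <- brute_overlap("chr1", fx$promoters$start[p],
                          fx$promoters$end[p], "chr1",
                          loops$start2[l], loops$end2[l])
      if ((o1 && p2) || (o2 && p1)) expected <- expected + 1
    }
  }
  # expected counts (ocr,loop,gene) triples incl. promoter OCRs also looped
  recovered <- sum(cres$n_loops)
  expect_equal(recovered, expected)
})

test_that("a single anchor covering OCR and promoter is not a contact", {
  fx <- .cre_fixture()
  # OCR inside G1 promoter; loop anchor1 covers both, anchor2 elsewhere
  ocrs <- toy_ocrs("chr1", 1500, 1900, ids = "inProm")
  loops <- toy_loops("chr1", 1000, 3000, 50000, 50500)
  expect_equal(nrow(define_cres(ocrs, loops, fx$promoters)), 0)
})

test_that("duplicate loops are deduplicated with a message", {
  fx <- .cre_fixture()
  ocrs <- toy_ocrs("chr1", c(50000, 1500), c(50500, 1900))
  loops <- toy_loops("chr1", c(49900, 49900), c(50400, 50400),
                     c(1200, 1200), c(2000, 2000))
  expect_message(cres <- define_cres(ocrs, loops, fx$promoters),
                 "deduplicated 1")
  expect_equal(cres$n_loops, 1)
})

test_that("removing a cRE's supporting loops removes the cRE", {
  set.seed(7)
  for (rep in 1:10) {
    cfg <- sim_config(seed = rep, n_genes = 30, n_ocr_per_cell = 60,
                      n_cell_types = 1, chrom_length = 2e6,
                      frac_ocr_looped = 0.3, n_sentinels_per_trait = 5,
                      proxies_per_sentinel = c(3, 8))
    g <- simulate_genome(cfg)
    cres <- define_cres(g$ocrs, g$loops, g$promoters)
    if (!nrow(cres)) next
    victim <- cres$cre_id[1]
    drop_loops <- unlist(strsplit(cres$loop_ids[cres$cre_id == victim], ","))
    pruned <- g$loops[!(g$loops$loop_id %in% drop_loops), ]
    again <- define_cres(g$ocrs, pruned, g$promoters)
    expect_false(victim %in% again$cre_id)
  }
})

test_that("partition categories obey the set algebra and flank merging", {
  fx <- .cre_fixture()
  ocrs <- toy_ocrs("chr1", c(1500, 50000, 70000), c(1900, 50500, 70500),
                   ids = c("pG1", "A", "B"))
  loops <- toy_loops("chr1", 49900, 50400, 1200, 2000)
  cres <- define_cres(ocrs, loops, fx$promoters)
  part <- partition_annotations(ocrs, cres, fx$promoters)
  sizes <- vapply(part$categories, nrow, integer(1))
  expect_equal(unname(sizes), c(3L, 1L, 1L, 1L, 1L))
  expect_equal(part$categories$NON_CRE_NON_PROM$peak_id, "B")
  expect_error(partition_annotations(ocrs, cres, fx$promoters, flank = -1),
               "flank")
})

test_that("a peak can be both promoter-overlapping and a cRE", {
  fx <- .cre_fixture()
  # OCR inside G1's promoter, looped to G2's promoter (both open)
  ocrs <- toy_ocrs("chr1", c(1500, 8600), c(1900, 9000),
                   ids = c("dual", "pG2"))
  loops <- toy_loops("chr1", 1400, 2000, 8499, 9000)
  cres <- define_cres(ocrs, loops, fx$promoters)
  expect_true("dual" %in% cres$cre_id)
  expect_equal(cres$gene_id[cres$cre_id == "dual"], "G2")
  part <- partition_annotations(ocrs, cres, fx$promoters)
  expect_true("dual" %in% part$categories$PROMOTER_OCR$peak_id)
  expect_true("dual" %in% part$categories$CRE$peak_id)
  expect_false("dual" %in% part$categories$NON_CRE_NON_PROM$peak_id)
})

test_that("flanked cREs 600 bp apart merge into one interval", {
  fx <- .cre_fixture()
  ocrs <- toy_ocrs("chr1", c(50000, 51100, 1500), c(50500, 51500, 1900),
                   ids = c("A", "B", "pG1"))
  loops <- toy_loops("chr1", c(49900, 51050), c(50400, 51200),
                     c(1200, 1200), c(2000, 2000))
  cres <- define_cres(ocrs, loops, fx$promoters)
  expect_setequal(unique(cres$cre_id), c("A", "B"))
  part <- partition_annotations(ocrs, cres, fx$promoters, flank = 500)
  fl <- part$categories$CRE_FLANK500
  expect_equal(nrow(fl), 1)
  # independent interval-arithmetic oracle
  oracle <- brute_merge(c(50000 - 500, 51100 - 500),
                        c(50500 + 500, 51500 + 500))
  expect_equal(fl$start, oracle$start)
  expect_equal(fl$end, oracle$end)
})

test_that("LDSC annotation export marks membership half-open and preserves
          row order and count", {
  part <- structure(list(cell_type = "cellA", categories = list(
    CRE = iv("chr1", 100, 200))), class = "annotation_partition")
  tmpl <- data.frame(chrom = "chr1", bp = c(50, 100, 150, 199, 200),
                     snp = sprintf("rs%d", 1:5), cm = 0)
  ann <- export_ldsc_annot(part, tmpl, "CRE")
  expect_equal(ann$ANNOT, c(0L, 1L, 1L, 1L, 0L))
  expect_equal(nrow(ann), nrow(tmpl))
  expect_equal(ann$SNP, tmpl$snp)

  part$categories$EMPTY <- iv(character(), integer(), integer())
  ann0 <- export_ldsc_annot(part, tmpl, "EMPTY")
  expect_equal(sum(ann0$ANNOT), 0)

  bad <- tmpl[c(2, 1, 3, 4, 5), ]
  expect_error(export_ldsc_annot(part, bad, "CRE"), "sorted")
})
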