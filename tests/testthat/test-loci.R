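.sent <- function(id, chrom, pos, trait = "T1") {
  data.frame(trait = trait, variant_id = id, chrom = chrom,
             pos = as.integer(pos), stringsAsFactors = FALSE)
}

.prox <- function(sent, chrom, pos) {
  data.frame(sentinel = sent, chrom = chrom, pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

.no_overlap <- function(loci) {
  for (ch in unique(loci$chrom)) {
    l <- loci[loci$chrom == ch, ]
    l <- l[order(l$start), ]
    if (nrow(l) > 1 && any(l$start[-1] < l$end[-nrow(l)])) return(FALSE)
  }
  TRUE
}

test_that("a single sentinel's locus is its proxy span plus the flank", {
  loci <- build_loci(.sent("s1", "chr1", 1000000),
                     .prox("s1", "chr1", c(990000, 1000000, 1010000)))
  expect_equal(nrow(loci), 1)
  expect_equal(loci$start, 990000 - 250000)
  expect_equal(loci$end, 1010000 + 1 + 250000)
})

test_that("high-LD co-resident sentinels merge; low-LD sentinels split at
          the proxy-span midpoint", {
  sents <- rbind(.sent("s1", "chr1", 1000000), .sent("s2", "chr1", 1300000))
  prox <- rbind(.prox("s1", "chr1", c(990000, 1010000)),
                .prox("s2", "chr1", c(1290000, 1310000)))
  ld_hi <- matrix(c(1, .9, .9, 1), 2, dimnames = list(c("s1", "s2"),
                                                      c("s1", "s2")))
  merged <- build_loci(sents, prox, ld_r2 = ld_hi)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_sentinels, 2)

  ld_lo <- matrix(c(1, .3, .3, 1), 2, dimnames = dimnames(ld_hi))
  split <- build_loci(sents, prox, ld_r2 = ld_lo)
  expect_equal(nrow(split), 2)
  expect_true(.no_overlap(split))
  # midpoint between span end (1010000+1) and next span start (1290000)
  cut <- floor((1010001 + 1290000) / 2)
  expect_equal(split$end[1], cut)
  expect_equal(split$start[2], cut)
  # outer bounds keep the full flanked extent
  expect_equal(split$start[1], 990000 - 250000)
  expect_equal(split$end[2], 1310000 + 1 + 250000)
})

test_that("missing LD entries for co-resident sentinels are reported by
          name", {
  sents <- rbind(.sent("s1", "chr1", 1000000), .sent("s2", "chr1", 1100000))
  prox <- rbind(.prox("s1", "chr1", 1000000), .prox("s2", "chr1", 1100000))
  expect_error(build_loci(sents, prox), "ld_r2")
  ld <- matrix(1, 1, 1, dimnames = list("s1", "s1"))
  expect_error(build_loci(sents, prox, ld_r2 = ld), "s1 and s2")
})

test_that("loci are non-overlapping, deterministic, and stable under
          re-merging on random configurations", {
  set.seed(41)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    ids <- sprintf("s%d", seq_len(n))
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    pos <- sample(5e5:9e6, n)
    sents <- do.call(rbind, lapply(seq_len(n), function(i)
      .sent(ids[i], chrom[i], pos[i])))
    prox <- do.call(rbind, lapply(seq_len(n), function(i)
      .prox(ids[i], chrom[i], pos[i] + sample(-40000:40000, sample(2:6, 1)))))
    ld <- matrix(runif(n * n), n, dimnames = list(ids, ids))
    ld[lower.tri(ld)] <- t(ld)[lower.tri(ld)]
    diag(ld) <- 1
    loci <- build_loci(sents, prox, ld_r2 = ld)
    expect_true(.no_overlap(loci))
    expect_identical(loci, build_loci(sents, prox, ld_r2 = ld))
    # every sentinel lands in exactly one locus
    all_members <- unlist(strsplit(loci$sentinels, ","))
    expect_setequal(all_members, ids)
    expect_equal(anyDuplicated(all_members), 0L)
  }
})

test_that("eGene assignment enforces locus membership, FDR, chromosome, and
          high-LD filters", {
  loci <- data.frame(locus_id = "locus_001", chrom = "chr1",
                     start = 0L, end = 1000000L, sentinels = "s1",
                     n_sentinels = 1L, provenance = "single",
                     stringsAsFactors = FALSE)
  prox <- data.frame(sentinel = "s1", proxy = c("v1", "v2"),
                     chrom = "chr1", pos = c(500L, 600L),
                     stringsAsFactors = FALSE)
  eq <- data.frame(variant_id = c("v1", "v2", "v3", "v1"),
                   chrom = c("chr1", "chr1", "chr1", "chr1"),
                   pos = c(500L, 600L, 2000000L, 500L),
                   gene_id = c("gA", "gB", "gOut", "gTrans"),
                   gene_chrom = c("chr1", "chr1", "chr1", "chr2"),
                   fdr = c(0.01, 0.2, 0.001, 0.01),
                   stringsAsFactors = FALSE)
  eg <- assign_egenes(loci, eq, proxies = prox)
  expect_equal(eg$gene_id, "gA")        # gB fails FDR, gOut outside,
                                        # gTrans on another chromosome
  eg2 <- assign_egenes(loci, eq, require_same_chrom = FALSE,
                       proxies = prox)
  expect_setequal(eg2$gene_id, c("gA", "gTrans"))
  # literal (typo) reading keeps the non-significant association instead
  eg3 <- assign_egenes(loci, eq, fdr_rule = "literal", proxies = prox)
  expect_equal(eg3$gene_id, "gB")
  # BH correction applied when only p-values are given
  eq$fdr <- NULL
  eq$pvalue <- c(1e-6, 0.9, 1e-6, 1e-6)
  eg4 <- assign_egenes(loci, eq, proxies = prox)
  expect_true("gA" %in% eg4$gene_id)
  expect_false("gB" %in% eg4$gene_id)
})

test_that("concordance reports the intersection against both denominators", {
  z <- concordance_summary(c("a", "b"), c("x", "y"))
  expect_equal(z$n_overlap, 0)
  expect_equal(z$pct_of_eqtl, 0)
  v2g <- sprintf("g%d", 1:200)
  eq <- sprintf("g%d", 1:50)
  z2 <- concordance_summary(v2g, eq)
  expect_equal(z2$pct_of_eqtl, 100)
  expect_equal(z2$pct_of_v2g, 25)
  set.seed(19)
  for (rep in 1:10) {
    a <- sample(sprintf("g%d", 1:60), sample(10:40, 1))
    b <- sample(sprintf("g%d", 1:60), sample(10:40, 1))
    z <- concordance_summary(a, b)
    expect_equal(z$n_overlap, length(intersect(a, b)))
    expect_equal(z$pct_of_v2g, 100 * length(intersect(a, b)) / length(a))
  }
})
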