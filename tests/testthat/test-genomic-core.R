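test_that("read_bed parses coordinates, ids, and rejects malformed lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tpk1", "chr2\t50\t80"), f)
  peaks <- read_bed(f, "cellA")
  expect_equal(peaks$chrom, c("chr1", "chr2"))
  expect_equal(peaks$start, c(100L, 50L))
  expect_equal(peaks$end, c(200L, 80L))
  expect_equal(peaks$peak_id, c("pk1", "chr2:50-80"))
  expect_equal(unique(peaks$cell_type), "cellA")

  writeLines(character(), f)
  expect_equal(nrow(read_bed(f, "cellA")), 0)

  writeLines("chr1\t200\t100", f)
  expect_error(read_bed(f, "cellA"), "line 1")
  writeLines(c("chr1\t10\t20", "chr1\t5"), f)
  expect_error(read_bed(f, "cellA"), "line 2")
})

test_that("read_loops handles ibed and bedpe, drops inter-chromosomal lines,
          and keeps duplicates", {
  f <- withr::local_tempfile(fileext = ".ibed")
  hdr <- paste(c("bait_chr", "bait_start", "bait_end", "bait_name",
                 "otherEnd_chr", "otherEnd_start", "otherEnd_end",
                 "otherEnd_name", "N_reads", "score"), collapse = "\t")
  line <- "chr2\t100\t500\tb1\tchr2\t9000\t9400\toe1\t12\t6.1"
  writeLines(c(hdr, line, line), f)
  lp <- read_loops(f, "ibed", "cellA", "pcc")
  expect_equal(nrow(lp), 2)               # no implicit dedup
  expect_equal(length(unique(lp$loop_id)), 2)
  expect_equal(lp$start1[1], 100L)
  expect_equal(lp$end2[1], 9400L)
  expect_equal(lp$score[1], 6.1)

  fb <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t10\t20\tchr1\t50\t60",
               "chr1\t10\t20\tchr5\t50\t60"), fb)
  expect_message(lpb <- read_loops(fb, "bedpe", "cellA", "hic"),
                 "dropped 1")
  expect_equal(nrow(lpb), 1)
  expect_equal(attr(lpb, "n_interchrom_dropped"), 1)

  writeLines(c(hdr), f)
  expect_error(read_loops(f, "ibed", "cellA", "pcc"), "no loop lines")
  writeLines("chr1\t1\t2", fb)
  expect_error(read_loops(fb, "bedpe", "cellA", "hic"), "6 columns")
})

test_that("BED and ibed round-trip exactly", {
  peaks <- toy_ocrs("chr1", c(10, 400), c(60, 900), ids = c("a", "b"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(peaks, f)
  back <- read_bed(f, "cellA")
  expect_equal(back[, c("chrom", "start", "end", "peak_id")],
               peaks[, c("chrom", "start", "end", "peak_id")])

  loops <- toy_loops("chr3", c(5, 100), c(50, 200), c(900, 1500),
                     c(950, 1600))
  fi <- withr::local_tempfile(fileext = ".ibed")
  write_ibed(loops, fi)
  back <- read_loops(fi, "ibed", "cellA", "pcc")
  expect_equal(back[, c("chrom", "start1", "end1", "start2", "end2")],
               loops[, c("chrom", "start1", "end1", "start2", "end2")])
})

test_that("make_promoters applies the -1500/+500 rule, mirrors on minus
          strand, and clamps at chromosome edges", {
  sizes <- c(chr1 = 1e6)
  g <- toy_genes("chr1", c(10000, 10000, 1000), c("+", "-", "+"))
  p <- make_promoters(g, chrom_sizes = sizes)
  expect_equal(p$start, c(8499L, 9500L, 0L))
  expect_equal(p$end, c(10499L, 11500L, 1499L))
  expect_error(make_promoters(toy_genes("chrX", 100), chrom_sizes = sizes),
               "chrX")
})

test_that("promoter windows contain their TSS and match input count", {
  sizes <- c(chr1 = 5e5, chr2 = 5e5)
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    g <- toy_genes(sample(c("chr1", "chr2"), n, replace = TRUE),
                   sample(3000:400000, n),
                   sample(c("+", "-"), n, replace = TRUE))
    p <- make_promoters(g, chrom_sizes = sizes)
    expect_equal(nrow(p), n)
    expect_true(all(p$start <= g$tss - 1 & g$tss - 1 < p$end))
    expect_true(all(p$end - p$start <= 2000))
  }
})

test_that("overlaps is half-open, chromosome-aware, and symmetric", {
  expect_true(overlaps(iv("chr1", 100, 200), iv("chr1", 199, 300)))
  expect_false(overlaps(iv("chr1", 100, 200), iv("chr1", 200, 300)))
  expect_false(overlaps(iv("chr1", 100, 200), iv("chr2", 100, 200)))
  set.seed(5)
  for (i in 1:50) {
    a <- iv("chr1", s <- sample(100, 1), s + sample(50, 1))
    b <- iv("chr1", s2 <- sample(100, 1), s2 + sample(50, 1))
    expect_identical(overlaps(a, b), overlaps(b, a))
    expect_identical(unname(overlaps(a, b)),
                     brute_overlap("chr1", a$start, a$end,
                                   "chr1", b$start, b$end))
  }
})

test_that("read_sumstats maps columns, converts OR to log-odds, and logs
          drops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(rsid = c("v1", "v2", "v3", "v4"),
                   CHR = "chr1", position = c(10, 20, NA, 40),
                   A1 = "A", A2 = "G",
                   OR = c(1.0, 2.0, 1.5, 1.2),
                   stderr = c(0.1, 0.2, 0.1, 0))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  cols <- list(variant = "rsid", chrom = "CHR", pos = "position",
               effect_allele = "A1", other_allele = "A2", or = "OR",
               se = "stderr")
  expect_message(ss <- read_sumstats(f, cols), "missing position")
  expect_equal(nrow(ss), 2)
  expect_equal(ss$beta[1], 0)
  expect_equal(ss$beta[2], log(2), tolerance = 1e-10)
  expect_equal(attr(ss, "n_dropped_pos"), 1)
  expect_equal(attr(ss, "n_dropped_se"), 1)
  expect_error(read_sumstats(f, list(variant = "nope")), "configuration")
})
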