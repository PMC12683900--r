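.uniform_pwm <- function(L = 4) {
  make_pwm(probs = matrix(0.25, nrow = L, ncol = 4), tf_name = "uniform")
}

.strong_pwm <- function() {
  counts <- matrix(c(90, 4, 3, 3,
                     2, 92, 3, 3,
                     3, 3, 91, 3,
                     88, 4, 4, 4,
                     3, 3, 3, 91,
                     4, 90, 3, 3), ncol = 4, byrow = TRUE)
  make_pwm(counts, tf_name = "strongTF")
}

test_that("IC scoring: uniform PWM scores 0 and the consensus dominates", {
  u <- .uniform_pwm()
  expect_equal(score_sequence(u, "ACGT"), 0)
  expect_equal(score_sequence(u, "TTTT"), 0)

  p97 <- make_pwm(probs = matrix(c(0.97, 0.01, 0.01, 0.01), nrow = 1),
                  tf_name = "single")
  expect_equal(score_sequence(p97, "A"), log2(0.97 / 0.25),
               tolerance = 1e-9)
  expect_equal(score_sequence(p97, "A"), 1.956, tolerance = 1e-3)

  pwm <- .strong_pwm()
  cons <- pwm_consensus(pwm)
  s_max <- score_sequence(pwm, cons)
  set.seed(2)
  for (i in 1:30) {
    seq <- paste(sample(c("A", "C", "G", "T"), pwm$length, replace = TRUE),
                 collapse = "")
    expect_lte(score_sequence(pwm, seq), s_max)
  }
  expect_error(score_sequence(pwm, "ACGTNN"), "ambiguous")
  expect_error(score_sequence(pwm, "ACG"), "length")
})

test_that("JASPAR PFM parsing accepts bracketed and bare rows", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0001 TFA",
               "A [ 10  2  0 ]",
               "C [  0  1  9 ]",
               "G [  0  6  1 ]",
               "T [  0  1  0 ]",
               ">MA0002 TFB",
               "5 5", "0 0", "5 5", "0 0"), f)
  pwms <- read_jaspar_pfm(f)
  expect_setequal(names(pwms), c("TFA", "TFB"))
  expect_equal(pwms$TFA$length, 3)
  expect_equal(pwms$TFB$length, 2)
  expect_equal(pwm_consensus(pwms$TFA), "AGC")
  expect_true(all(abs(rowSums(pwms$TFA$probs) - 1) < 1e-9))
})

test_that("score p-values are exact for short motifs and monotone", {
  u <- .uniform_pwm()
  expect_equal(pwm_score_pvalue(u, 0), 1)

  p97 <- make_pwm(probs = matrix(c(0.97, 0.01, 0.01, 0.01), nrow = 1))
  expect_equal(pwm_score_pvalue(p97, score_sequence(p97, "A")), 0.25)

  set.seed(27)
  for (L in c(2, 4, 6)) {
    counts <- matrix(sample(1:50, 4 * L, replace = TRUE), ncol = 4)
    pwm <- make_pwm(counts, tf_name = sprintf("rand%d", L))
    scores <- if (L == 2) {
      grid <- expand.grid(1:4, 1:4)
      apply(grid, 1, function(ix) {
        sm <- log2(pwm$probs / 0.25)
        sm[1, ix[1]] + sm[2, ix[2]]
      })
    } else {
      sapply(1:10, function(i) score_sequence(
        pwm, paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")))
    }
    for (s in scores)
      expect_equal(pwm_score_pvalue(pwm, s), brute_pwm_pvalue(pwm, s),
                   tolerance = 2 / 10000)
    ss <- sort(scores)
    pv <- pwm_score_pvalue(pwm, ss)
    expect_true(all(diff(pv) <= 1e-12))
  }
})

test_that("binned convolution approximates the tail for long motifs", {
  set.seed(8)
  counts <- matrix(sample(1:50, 4 * 12, replace = TRUE), ncol = 4)
  pwm <- make_pwm(counts, tf_name = "long")
  cons <- pwm_consensus(pwm)
  p_top <- pwm_score_pvalue(pwm, score_sequence(pwm, cons))
  expect_gt(p_top, 0)
  expect_lt(p_top, 1e-3)
  expect_equal(pwm_score_pvalue(pwm, -1e9), 1)
  expect_error(pwm_score_pvalue(pwm, 0, resolution = 10), "resolution")
})

test_that("variant scanning reports disruption with the expected sign,
          p-value gate, and strand symmetry", {
  pwm <- .strong_pwm()
  cons <- pwm_consensus(pwm)
  ref <- paste0("ACGT", cons, "ACGT")
  alt <- ref
  substr(alt, 7, 7) <- "T"   # break the third motif column (G)
  hits <- scan_variant(pwm, ref, alt, variant_id = "v1")
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$delta < 0))
  expect_true(all(pmin(hits$p_ref, hits$p_alt) <= 0.0005))
  expect_true(all(hits$delta == hits$score_alt - hits$score_ref))

  # swapped alleles negate the deltas of the same windows
  back <- scan_variant(pwm, alt, ref, variant_id = "v1")
  key <- function(h) paste(h$strand, h$offset)
  common <- intersect(key(hits), key(back))
  expect_gt(length(common), 0)
  for (k in common) {
    expect_equal(hits$delta[key(hits) == k], -back$delta[key(back) == k],
                 tolerance = 1e-12)
  }

  expect_error(scan_variant(pwm, "ACGTAA", "ACCTCA"), "exactly one")
  expect_error(scan_variant(pwm, "ACG", "ACT"), "shorter")

  # no window passes the gate when both alleles score poorly
  weak <- scan_variant(pwm, "TTTTTTTTTTTTTT", "TTTTTTGTTTTTTT")
  expect_equal(nrow(weak), 0)
})

test_that("palindromic PWMs hit both strands identically", {
  # perfect palindrome: ACGT-consensus with reverse-complement symmetry
  probs <- rbind(c(0.85, 0.05, 0.05, 0.05),   # A
                 c(0.05, 0.85, 0.05, 0.05),   # C
                 c(0.05, 0.05, 0.85, 0.05),   # G
                 c(0.05, 0.05, 0.05, 0.85))   # T
  pwm <- make_pwm(probs = probs, tf_name = "palindrome")
  ref <- "AAACGTAAA"
  alt <- "AAACTTAAA"
  hits <- scan_variant(pwm, ref, alt, threshold_p = 0.01)
  plus <- hits[hits$strand == "+", ]
  minus <- hits[hits$strand == "-", ]
  expect_equal(nrow(plus), nrow(minus))
  expect_setequal(round(plus$score_ref, 9), round(minus$score_ref, 9))
})
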