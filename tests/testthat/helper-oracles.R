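# Fixture builders and independent oracles used across the suite.
# Oracles deliberately avoid the code paths they check: brute-force
# enumeration, plain set arithmetic, and direct interval arithmetic.

iv <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

toy_ocrs <- function(chrom, starts, ends, ids = NULL, cell_type = "cellA") {
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(ends),
             peak_id = if (is.null(ids)) sprintf("pk%d", seq_along(starts))
                       else ids,
             cell_type = cell_type, stringsAsFactors = FALSE)
}

toy_loops <- function(chrom, s1, e1, s2, e2, cell_type = "cellA",
                      ids = NULL) {
  data.frame(loop_id = if (is.null(ids)) sprintf("L%d", seq_along(s1))
                       else ids,
             cell_type = cell_type, source = "pcc", chrom = chrom,
             start1 = as.integer(s1), end1 = as.integer(e1),
             start2 = as.integer(s2), end2 = as.integer(e2),
             score = 6, stringsAsFactors = FALSE)
}

toy_genes <- function(chrom, tss, strand = NULL, ids = NULL) {
  n <- length(tss)
  data.frame(gene_id = if (is.null(ids)) sprintf("G%d", seq_len(n)) else ids,
             gene_name = if (is.null(ids)) sprintf("G%d", seq_len(n))
                         else ids,
             chrom = chrom, tss = as.integer(tss),
             strand = if (is.null(strand)) rep("+", n) else strand,
             stringsAsFactors = FALSE)
}

# brute-force single-causal colocalization: explicit enumeration of every
# configuration (H0; causal SNP i for one or both datasets)
brute_coloc <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  a1 <- exp(l1); a2 <- exp(l2)
  h0 <- 1
  h1 <- p1 * sum(a1)
  h2 <- p2 * sum(a2)
  h3 <- 0
  for (i in seq_along(a1)) for (j in seq_along(a2))
    if (i != j) h3 <- h3 + p1 * p2 * a1[i] * a2[j]
  h4 <- p12 * sum(a1 * a2)
  w <- c(h0, h1, h2, h3, h4)
  stats::setNames(w / sum(w), c("PP.H0", "PP.H1", "PP.H2", "PP.H3", "PP.H4"))
}

# exhaustive PWM score-distribution p-value: enumerate all 4^L sequences
brute_pwm_pvalue <- function(pwm, score) {
  L <- pwm$length
  grid <- do.call(expand.grid, rep(list(1:4), L))
  sm <- log2(pwm$probs / rep(pwm$background, each = L))
  tot <- apply(grid, 1, function(idx) sum(sm[cbind(seq_len(L), idx)]))
  prob <- apply(grid, 1, function(idx) prod(pwm$background[idx]))
  sum(prob[tot >= score - 1e-9])
}

# independent half-open overlap on plain vectors
brute_overlap <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 && s1 < e2 && s2 < e1
}

# interval union via position flags (small coordinates only)
brute_merge <- function(starts, ends) {
  covered <- rep(FALSE, max(ends))
  for (i in seq_along(starts)) covered[(starts[i] + 1):ends[i]] <- TRUE
  r <- rle(covered)
  stops <- cumsum(r$lengths)
  begins <- c(0, stops[-length(stops)])
  data.frame(start = begins[r$values], end = stops[r$values])
}

random_pairs <- function(n = 60, n_var = 15, n_gene = 10, n_trait = 3,
                        n_cell = 4) {
  data.frame(trait = sample(sprintf("t%d", 1:n_trait), n, replace = TRUE),
             sentinel = "s", proxy = sample(sprintf("v%d", 1:n_var), n,
                                            replace = TRUE),
             cell_type = sample(sprintf("c%d", 1:n_cell), n, replace = TRUE),
             gene_id = sample(sprintf("g%d", 1:n_gene), n, replace = TRUE),
             stringsAsFactors = FALSE)
}
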