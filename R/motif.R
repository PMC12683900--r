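# Allele-specific transcription-factor binding-site disruption scoring.
#
# Position frequency matrices are converted to probabilities with a
# pseudocount, scored as information-content log2-odds against an even
# background, and p-values come from the exact distribution of the score of
# a background-drawn sequence (position-wise convolution of the four-point
# per-column score distributions).

.BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from counts or probabilities
#'
#' Counts get a pseudocount of `pseudocount / 4` added to every cell before
#' row normalization, so no probability is exactly zero. Probabilities are
#' accepted as-is (rows must already sum to 1).
#'
#' @param counts Positions x 4 numeric matrix (columns A, C, G, T), or `NULL`
#'   when `probs` is given.
#' @param tf_name Transcription-factor name.
#' @param pseudocount Total pseudocount per position (default 0.8).
#' @param background Background base probabilities (default even, 0.25 each).
#' @param probs Optional pre-normalized probability matrix (positions x 4).
#' @return Object of class `pwm`: list with `tf_name`, `probs`, `background`,
#'   `pseudocount`, `length`.
#' @export
make_pwm <- function(counts = NULL, tf_name = "motif", pseudocount = 0.8,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                     probs = NULL) {
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-9)
  if (is.null(probs)) {
    stopifnot(!is.null(counts), ncol(counts) == 4)
    counts <- counts + pseudocount / 4
    probs <- counts / rowSums(counts)
  } else {
    stopifnot(ncol(probs) == 4)
    if (any(abs(rowSums(probs) - 1) > 1e-9))
      stop("probability rows must sum to 1")
    if (any(probs <= 0))
      stop("probabilities must be > 0 (apply a pseudocount)")
  }
  colnames(probs) <- .BASES
  structure(list(tf_name = tf_name, probs = unname(probs),
                 background = unname(background),
                 pseudocount = pseudocount, length = nrow(probs)),
            class = "pwm")
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the `>ID NAME` header followed by four base rows, either
#' `A [ 1 2 3 ]` style or four bare count rows in A, C, G, T order.
#'
#' @param path PFM text file, possibly holding several motifs.
#' @param pseudocount,background Passed to [make_pwm()].
#' @return Named list of `pwm` objects (names = TF names).
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.8,
                            background = c(0.25, 0.25, 0.25, 0.25)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' header in PFM file: ", path)
  out <- list()
  for (i in seq_along(starts)) {
    from <- starts[i] + 1
    to <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    name <- if (length(toks) >= 2) toks[2] else toks[1]
    rows <- lines[from:to]
    if (length(rows) != 4)
      stop("PFM for ", name, ": expected 4 base rows, got ", length(rows))
    parse_row <- function(r) {
      r <- gsub("^[ACGTacgt]\\s*", "", r)
      r <- gsub("[][]", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }
    mat <- lapply(rows, parse_row)
    if (length(unique(lengths(mat))) != 1)
      stop("PFM for ", name, ": ragged count rows")
    counts <- t(do.call(rbind, mat))   # positions x 4 (A C G T)
    out[[name]] <- make_pwm(counts, tf_name = name,
                            pseudocount = pseudocount,
                            background = background)
  }
  out
}

.base_index <- function(seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  idx <- match(b, .BASES)
  if (anyNA(idx))
    stop("ambiguous or invalid base '", b[which(is.na(idx))[1]],
         "' (no IUPAC expansion)")
  idx
}

# positions x 4 matrix of per-column log2-odds scores
.score_matrix <- function(pwm) {
  log2(pwm$probs / rep(pwm$background, each = pwm$length))
}

#' Information-content score of a sequence under a PWM
#'
#' Sum over motif positions of `log2(p[pos, base] / background[base])`.
#'
#' @param pwm A `pwm` object.
#' @param seq Character string over A/C/G/T with `nchar(seq) == pwm$length`.
#' @return Numeric log2-odds score.
#' @export
score_sequence <- function(pwm, seq) {
  idx <- .base_index(seq)
  if (length(idx) != pwm$length)
    stop("sequence length ", length(idx), " != motif length ", pwm$length)
  sm <- .score_matrix(pwm)
  sum(sm[cbind(seq_len(pwm$length), idx)])
}

#' Consensus sequence of a PWM
#' @param pwm A `pwm` object.
#' @return Character string of per-position maximum-probability bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(.BASES[apply(pwm$probs, 1, which.max)], collapse = "")
}

# Exact (or binned) distribution of the background score. Returns list
# (vals, probs) sorted ascending. Exact value-merging convolution when the
# outcome space is small (4^L <= 2^16); otherwise integer-binned convolution
# at `resolution` bins across the score range.
.pwm_score_distribution <- function(pwm, resolution = 10000) {
  sm <- .score_matrix(pwm)
  bg <- pwm$background
  L <- pwm$length
  if (4^L <= 2^16) {
    vals <- 0; probs <- 1
    for (l in seq_len(L)) {
      nv <- as.vector(outer(vals, sm[l, ], `+`))
      np <- as.vector(outer(probs, bg, `*`))
      key <- round(nv, 9)
      agg <- rowsum(np, key)
      vals <- as.numeric(rownames(agg))
      probs <- as.vector(agg)
      o <- order(vals); vals <- vals[o]; probs <- probs[o]
    }
    # tie tolerance covers the rounding drift of the merged values, and is
    # far below the spacing of distinct log2-odds sums
    return(list(vals = vals, probs = probs, exact = TRUE, tol = 1e-6))
  }
  rng <- sum(apply(sm, 1, max)) - sum(apply(sm, 1, min))
  if (rng < 1e-12) {
    return(list(vals = sum(sm[, 1]), probs = 1, exact = TRUE, tol = 1e-6))
  }
  delta <- rng / resolution
  k <- round(sm / delta)                  # integer per-column scores
  cur_lo <- 0; cur <- 1                    # distribution of partial sum
  for (l in seq_len(L)) {
    kl <- k[l, ]
    new_lo <- cur_lo + min(kl)
    new_hi <- cur_lo + length(cur) - 1 + max(kl)
    new <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      off <- cur_lo + kl[b] - new_lo
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + cur * bg[b]
    }
    cur <- new; cur_lo <- new_lo
  }
  vals <- (cur_lo + seq_along(cur) - 1) * delta
  keep <- cur > 0
  list(vals = vals[keep], probs = cur[keep], exact = FALSE,
       tol = (L + 1) * delta / 2)
}

#' Exact p-value of a PWM score under the background model
#'
#' Returns `P(S >= score)` where `S` is the score of a random sequence drawn
#' from the background base distribution, computed by position-wise
#' convolution of the per-column score distributions. Monotone non-increasing
#' in `score`. The distribution is exact for motifs up to 8 bp; longer motifs
#' are convolved on a `resolution`-bin discretization of the score range.
#'
#' @param pwm A `pwm` object.
#' @param score Score(s) at which to evaluate the upper tail.
#' @param resolution Number of discretization bins (>= 100) for long motifs.
#' @return Numeric p-value(s) in (0, 1].
#' @export
pwm_score_pvalue <- function(pwm, score, resolution = 10000) {
  if (resolution < 100) stop("resolution must be >= 100")
  d <- .pwm_score_distribution(pwm, resolution)
  vapply(score, function(s) sum(d$probs[d$vals >= s - d$tol]), numeric(1))
}

#' Reverse complement of a DNA string
#' @param seq Character string over A/C/G/T.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(comp[strsplit(toupper(seq), "")[[1]]])), collapse = "")
}

#' Scan a variant for allele-specific motif disruption
#'
#' Slides the motif over every window of the reference/alternate context that
#' covers the variant, on both strands (minus-strand windows are scored on
#' the reverse complement). A window is reported when the more significant of
#' the two allele p-values passes `threshold_p` (`require_both = TRUE`
#' demands both). The disruption effect classifies
#' `delta = score_alt - score_ref`: `strong` when `|delta| >= strong_delta`
#' bits, `weak` when `weak_delta <= |delta| < strong_delta`, else `neutral`.
#'
#' @param pwm A `pwm` object.
#' @param ref_context,alt_context Equal-length A/C/G/T strings differing at
#'   exactly one position (the variant).
#' @param variant_id Identifier copied into the output.
#' @param threshold_p Scoring p-value threshold (default 5e-4).
#' @param require_both Require both alleles to pass the threshold.
#' @param strong_delta,weak_delta Effect-size cutoffs in bits (defaults 1
#'   and 0.4).
#' @param resolution Passed to the p-value convolution.
#' @return data.frame of motif hits: `tf_name`, `variant_id`, `strand`,
#'   `offset` (0-based variant position within the motif window),
#'   `score_ref`, `score_alt`, `delta`, `p_ref`, `p_alt`, `effect`.
#' @export
scan_variant <- function(pwm, ref_context, alt_context, variant_id = "variant",
                         threshold_p = 0.0005, require_both = FALSE,
                         strong_delta = 1, weak_delta = 0.4,
                         resolution = 10000) {
  rc <- toupper(ref_context); ac <- toupper(alt_context)
  if (nchar(rc) != nchar(ac))
    stop("ref and alt contexts differ in length")
  rb <- strsplit(rc, "")[[1]]; ab <- strsplit(ac, "")[[1]]
  diffs <- which(rb != ab)
  if (length(diffs) != 1)
    stop("contexts must differ at exactly one position, found ",
         length(diffs))
  v <- diffs
  L <- pwm$length
  n <- nchar(rc)
  if (L > n) stop("context shorter than motif")
  d <- .pwm_score_distribution(pwm, resolution)
  pval <- function(s) sum(d$probs[d$vals >= s - d$tol])
  offsets <- seq(max(1, v - L + 1), min(v, n - L + 1))
  hits <- list()
  for (i in offsets) {
    win_ref <- substr(rc, i, i + L - 1)
    win_alt <- substr(ac, i, i + L - 1)
    for (strand in c("+", "-")) {
      sr <- if (strand == "+") score_sequence(pwm, win_ref)
            else score_sequence(pwm, revcomp(win_ref))
      sa <- if (strand == "+") score_sequence(pwm, win_alt)
            else score_sequence(pwm, revcomp(win_alt))
      pr <- pval(sr); pa <- pval(sa)
      pass <- if (require_both) max(pr, pa) <= threshold_p
              else min(pr, pa) <= threshold_p
      if (!pass) next
      delta <- sa - sr
      effect <- if (abs(delta) >= strong_delta) "strong"
                else if (abs(delta) >= weak_delta) "weak" else "neutral"
      hits[[length(hits) + 1]] <-
        data.frame(tf_name = pwm$tf_name, variant_id = variant_id,
                   strand = strand, offset = v - i,
                   score_ref = sr, score_alt = sa, delta = delta,
                   p_ref = pr, p_alt = pa, effect = effect,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(tf_name = character(), variant_id = character(),
                      strand = character(), offset = integer(),
                      score_ref = numeric(), score_alt = numeric(),
                      delta = numeric(), p_ref = numeric(),
                      p_alt = numeric(), effect = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
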