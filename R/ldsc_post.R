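# Post-processing of stratified LD-score regression (S-LDSC) outputs.
# The regression itself runs externally; this module parses its .results
# tables and reimplements the two summary statistics used to compare
# annotations: heritability enrichment and the standardized per-SNP effect
# size tau-star, plus the cross-category one-sided comparison test.

#' Parse an S-LDSC .results table
#'
#' @param path Whitespace-delimited table with header containing `Category`,
#'   `Prop._SNPs`, `Prop._h2`, `Enrichment`, `Enrichment_std_error`,
#'   `Enrichment_p`, `Coefficient`, `Coefficient_std_error`.
#' @param baseline_pattern Regex marking baseline-model categories; matching
#'   rows are retained but flagged `is_baseline = TRUE`.
#' @param tol Relative tolerance for the internal consistency check
#'   `Enrichment ~ Prop._h2 / Prop._SNPs`; violations raise a warning.
#' @return data.frame with columns `category`, `prop_snps`, `prop_h2`,
#'   `enrichment`, `enrichment_se`, `enrichment_p`, `tau`, `tau_se`,
#'   `is_baseline`.
#' @export
parse_ldsc_results <- function(path, baseline_pattern = "^(base|L2_)",
                               tol = 0.05) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("Category", "Prop._SNPs", "Prop._h2", "Enrichment",
            "Enrichment_std_error", "Enrichment_p", "Coefficient",
            "Coefficient_std_error")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(".results format error, missing field(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(df)) stop("empty .results table: ", path)
  out <- data.frame(category = df$Category,
                    prop_snps = df$Prop._SNPs, prop_h2 = df$Prop._h2,
                    enrichment = df$Enrichment,
                    enrichment_se = df$Enrichment_std_error,
                    enrichment_p = df$Enrichment_p,
                    tau = df$Coefficient, tau_se = df$Coefficient_std_error,
                    is_baseline = grepl(baseline_pattern, df$Category),
                    stringsAsFactors = FALSE)
  implied <- out$prop_h2 / out$prop_snps
  off <- abs(out$enrichment - implied) >
    tol * pmax(1, abs(out$enrichment))
  if (any(off, na.rm = TRUE))
    warning("enrichment column inconsistent with Prop._h2/Prop._SNPs for ",
            sum(off, na.rm = TRUE), " row(s)")
  out
}

#' Heritability enrichment
#'
#' Enrichment of an annotation is its share of SNP heritability over its
#' share of SNPs, \eqn{(h^2_c/h^2_g) / (M_c/M)}. Negative `prop_h2` yields
#' negative enrichment, which S-LDSC permits.
#'
#' @param prop_h2 Proportion of heritability in the category (may be
#'   negative or exceed 1).
#' @param prop_snps Proportion of reference SNPs in the category (> 0).
#' @return Numeric enrichment, vectorized.
#' @export
compute_enrichment <- function(prop_h2, prop_snps) {
  if (any(prop_snps <= 0)) stop("prop_snps must be > 0")
  prop_h2 / prop_snps
}

#' Standardized annotation effect size tau-star
#'
#' \deqn{\tau^* = \tau \cdot sd_c \cdot M / h^2_g}
#' where \eqn{\tau} is the per-SNP coefficient, \eqn{sd_c} the standard
#' deviation of the annotation indicator across reference SNPs, \eqn{M} the
#' reference SNP count, and \eqn{h^2_g} the total SNP heritability (liability
#' scale when the regression was run with prevalence flags). The standard
#' error propagates by the same factor: pass `tau_se` to standardize it.
#'
#' @param tau Per-SNP coefficient (or its SE).
#' @param sd_c Annotation standard deviation, in `[0, 0.5]` for a binary
#'   annotation.
#' @param M Reference SNP count (> 0).
#' @param h2g Total SNP heritability (> 0).
#' @return Numeric tau-star, vectorized.
#' @export
compute_tau_star <- function(tau, sd_c, M, h2g) {
  if (any(M <= 0)) stop("M must be > 0")
  if (any(h2g <= 0)) stop("h2g must be > 0")
  if (any(sd_c < 0)) stop("sd_c must be >= 0")
  tau * sd_c * M / h2g
}

#' One-sided comparison of annotation categories against a reference
#'
#' For each non-reference category, a Welch two-sample t-test of the
#' alternative that its mean per-trait enrichment (or tau-star) is *less*
#' than the reference category's. Vectors are paired by trait across
#' categories and must have equal length >= 2.
#'
#' @param values Named list of numeric vectors (one per category, same trait
#'   order) or a numeric matrix with traits in rows and categories in columns.
#' @param reference Name of the reference category (default `"CRE"`).
#' @return data.frame with `category`, `t`, `df`, `p`, `significant`
#'   (p < 0.05); the number of significant comparisons is attached as
#'   attribute `"n_significant"`.
#' @export
compare_categories <- function(values, reference = "CRE") {
  if (is.matrix(values))
    values <- lapply(stats::setNames(seq_len(ncol(values)),
                                     colnames(values)),
                     function(j) values[, j])
  if (!reference %in% names(values))
    stop("reference category '", reference, "' not present")
  lens <- lengths(values)
  if (length(unique(lens)) != 1)
    stop("category vectors must be paired by trait (equal lengths)")
  if (lens[1] < 2)
    stop("need >= 2 traits per category for a t-test")
  ref <- values[[reference]]
  others <- setdiff(names(values), reference)
  res <- lapply(others, function(cat) {
    tt <- stats::t.test(values[[cat]], ref, alternative = "less",
                        var.equal = FALSE)
    data.frame(category = cat, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               significant = tt$p.value < 0.05, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_significant") <- sum(out$significant)
  out
}
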