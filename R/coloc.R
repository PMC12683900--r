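# Single-causal approximate-Bayes-factor (ABF) colocalization between a GWAS
# trait and an eQTL dataset within one locus-gene context. All hypothesis
# arithmetic is carried out in log space with logsumexp for stability.

#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x) || all(x == -Inf)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf-safe; tiny negative residuals from
# rounding collapse to -Inf
.logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Wakefield's log approximate Bayes factor for a single association
#'
#' With observed effect `beta`, standard error `se` (variance \eqn{V = se^2}),
#' prior effect variance `W`, and \eqn{z = beta/se}, \eqn{r = W/(V+W)}:
#' \deqn{\log ABF = \tfrac12\left(\log(1-r) + z^2 r\right)}
#' Positive values favor association over the null.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @param W Prior variance of the true effect (e.g. `0.15^2` for a
#'   quantitative trait, `0.2^2` for case-control log-odds).
#' @return Numeric log-ABF, vectorized.
#' @export
wakefield_labf <- function(beta, se, W) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || !is.finite(W))
    stop("non-finite inputs to wakefield_labf")
  if (any(se <= 0)) stop("se must be > 0")
  if (W < 0) stop("W must be >= 0")
  V <- se^2
  z2 <- (beta / se)^2
  r <- W / (V + W)
  0.5 * (log1p(-r) + z2 * r)
}

#' Priors for single-causal colocalization
#'
#' `p1`/`p2` are the per-SNP prior probabilities of association with the
#' trait / the eQTL alone; `p12` with both. `sd_quant` and `sd_cc` are the
#' prior standard deviations of the true effect for quantitative and
#' case-control datasets (variances \eqn{0.15^2} and \eqn{0.2^2}).
#'
#' @param p1,p2,p12 Per-SNP priors; requires `0 < p12 <= min(p1, p2)` and
#'   `p1 + p2 + p12 < 0.1`.
#' @param sd_quant,sd_cc Prior effect SDs.
#' @return List of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         sd_quant = 0.15, sd_cc = 0.2) {
  if (!(p12 > 0 && p12 <= min(p1, p2)))
    stop("require 0 < p12 <= min(p1, p2)")
  if (p1 + p2 + p12 >= 0.1)
    stop("priors implausibly large: p1 + p2 + p12 must be << 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12,
                 sd_quant = sd_quant, sd_cc = sd_cc),
            class = "coloc_priors")
}

#' Single-causal ABF colocalization of a trait and an eQTL dataset
#'
#' Tests the five hypotheses of the single-causal-variant model within one
#' locus: H0 no association; H1/H2 association with only the trait / only
#' the eQTL; H3 both, distinct causal variants; H4 both, one shared causal
#' variant. Per-SNP log-ABFs are computed with [wakefield_labf()], the prior
#' effect variance chosen by dataset type, and the hypothesis sums assembled
#' in log space:
#' \deqn{S_1 = \log p_1 + \mathrm{lse}(l_1),\quad
#'       S_4 = \log p_{12} + \mathrm{lse}(l_1 + l_2),}
#' \deqn{S_3 = \log p_1 + \log p_2 +
#'       \log\!\big(\textstyle\sum_i e^{l_{1i}} \sum_j e^{l_{2j}}
#'                  - \sum_i e^{l_{1i}+l_{2i}}\big)}
#' and posteriors are the softmax over \eqn{\{0, S_1, S_2, S_3, S_4\}}.
#' With a single SNP the \eqn{i \ne j} sum is empty, so PP.H3 = 0 exactly.
#'
#' @param trait_stats data.frame with `variant_id`, `beta`, `se` for the
#'   GWAS side (unique variant ids).
#' @param eqtl_stats Same columns for the eQTL side; variants are matched on
#'   `variant_id` and at least one must be shared.
#' @param priors A [coloc_priors()] object.
#' @param trait_type,eqtl_type `"cc"` (case-control) or `"quant"`; selects
#'   the prior effect variance per dataset.
#' @return Object of class `coloc_result`: list with `nsnps`, `summary`
#'   (named numeric `PP.H0`...`PP.H4`), `per_snp` (data.frame `variant_id`,
#'   `labf1`, `labf2`, `snp_pp_h4`), and `priors`.
#' @export
coloc_abf <- function(trait_stats, eqtl_stats, priors = coloc_priors(),
                      trait_type = c("cc", "quant"),
                      eqtl_type = c("quant", "cc")) {
  trait_type <- match.arg(trait_type)
  eqtl_type <- match.arg(eqtl_type)
  stopifnot(inherits(priors, "coloc_priors"))
  if (anyDuplicated(trait_stats$variant_id))
    stop("duplicated variant ids in trait_stats")
  if (anyDuplicated(eqtl_stats$variant_id))
    stop("duplicated variant ids in eqtl_stats")
  shared <- intersect(trait_stats$variant_id, eqtl_stats$variant_id)
  if (!length(shared)) stop("no shared variants between datasets")
  t1 <- trait_stats[match(shared, trait_stats$variant_id), ]
  t2 <- eqtl_stats[match(shared, eqtl_stats$variant_id), ]
  W1 <- if (trait_type == "cc") priors$sd_cc^2 else priors$sd_quant^2
  W2 <- if (eqtl_type == "cc") priors$sd_cc^2 else priors$sd_quant^2
  l1 <- wakefield_labf(t1$beta, t1$se, W1)
  l2 <- wakefield_labf(t2$beta, t2$se, W2)

  lse1 <- logsumexp(l1)
  lse2 <- logsumexp(l2)
  lse12 <- logsumexp(l1 + l2)
  S <- c(H0 = 0,
         H1 = log(priors$p1) + lse1,
         H2 = log(priors$p2) + lse2,
         H3 = log(priors$p1) + log(priors$p2) +
              .logdiffexp(lse1 + lse2, lse12),
         H4 = log(priors$p12) + lse12)
  m <- max(S)
  pp <- exp(S - m) / sum(exp(S - m))
  names(pp) <- paste0("PP.", names(S))
  snp_pp <- exp(l1 + l2 - lse12)
  per_snp <- data.frame(variant_id = shared, labf1 = l1, labf2 = l2,
                        snp_pp_h4 = snp_pp, stringsAsFactors = FALSE)
  structure(list(nsnps = length(shared), summary = pp, per_snp = per_snp,
                 priors = priors), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Single-causal colocalization over %d shared SNP(s)\n",
              x$nsnps))
  print(round(x$summary, 4))
  top <- x$per_snp[which.max(x$per_snp$snp_pp_h4), ]
  cat(sprintf("  top shared-causal candidate: %s (SNP.PP.H4 = %.3f)\n",
              top$variant_id, top$snp_pp_h4))
  invisible(x)
}
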