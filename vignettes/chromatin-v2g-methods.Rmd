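---
title: "Methods: 3D chromatin-based variant-to-gene mapping"
author: "chromV2G"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D chromatin-based variant-to-gene mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

Most genome-wide-significant GWAS variants for autoimmune disease are
non-coding, and the gene nearest to a lead SNP is frequently not the gene it
regulates. chromV2G implements a variant-to-gene (V2G) strategy that resolves
this through physical chromatin contact: a variant is assigned to a gene when
it falls in accessible chromatin that loops to that gene's promoter in a given
cell type. This vignette documents the models, conventions, parameters and
design choices; the README shows the worked example.

## Coordinate model

All intervals are 0-based half-open `[start, end)`, the BED convention, with
overlap defined as at least one shared base — abutting intervals do not
overlap. TSS tables are 1-based and converted on read. Variant positions are
0-based points (dbSNP-style), so a variant at position $p$ lies inside
`[start, end)` iff $start \le p < end$; this single rule governs LDSC
annotation membership, proxy-in-cRE tests and locus membership. Keeping one
convention across BED, BEDPE/ibed and variant tables is what prevents
off-by-one drift between modules.

## cis-regulatory elements

A promoter window spans $-1500/+500$ bp around the TSS, oriented by gene
strand and clamped (not errored) at chromosome boundaries — synthetic small
genomes routinely place genes near contig edges. An open chromatin region
(OCR; an ATAC-seq peak) becomes a cRE for gene $g$ when one anchor of a
chromatin loop overlaps the OCR and the *other* anchor overlaps a promoter
window of $g$. Three deliberate choices:

* **Anchor overlap needs one base**, with no minimum-fraction requirement;
  nothing in the underlying assays dictates a fraction and one base is the
  simplest defensible rule.
* **Self-contacts are excluded**: a single anchor covering both the OCR and
  the promoter is not evidence of looping — contact means reaching a
  *distant* promoter through the paired anchor.
* **`require_open_promoter` defaults to TRUE**: the contacted promoter must
  itself overlap an OCR of the same cell type. The flag exists because the
  bare cRE definition does not force it, but promoters without accessible
  chromatin are unlikely to be active regulatory targets.

Duplicate loops are kept by the parsers (lossless reading) and deduplicated,
with a logged count, at cRE definition time.

For stratified LD-score regression the open chromatin of each cell type is
partitioned into five annotation categories: all OCRs; promoter-overlapping
OCRs; cREs; cREs flanked by ±500 bp (merged where overlapping — membership
is per-SNP, so merging only affects bookkeeping); and OCRs that are neither
cREs nor promoter-overlapping, the negative control. The first three plus
the negative control cover all peaks; categories are not mutually exclusive
by design. The regression itself is external; this package writes the
`.annot` inputs and post-processes `.results` outputs.

## Heritability post-processing

Enrichment of category $c$ is $(h^2_c/h^2_g)/(M_c/M)$ — the share of SNP
heritability over the share of SNPs; negative values are legal and occur for
depleted annotations. The standardized effect size is

$$\tau^*_c = \tau_c \cdot sd_c \cdot M / h^2_g,$$

with $\tau_c$ the per-SNP conditional coefficient, $sd_c$ the standard
deviation of the annotation indicator over reference SNPs, $M$ the reference
SNP count and $h^2_g$ total SNP heritability (liability scale when the
upstream regression was run with prevalence flags; no re-conversion is done
here). The SE propagates coefficient-wise by the same factor, without
covariance terms, matching the standardization being applied per coefficient.
Cross-category comparison uses a one-sided (lesser) Welch $t$-test of each
category against the cRE reference, paired by trait. Welch was chosen over
Student because per-trait enrichment variances differ substantially between
annotation categories; the test pools across traits within one cell type
(the alternative pooling, across cell types per trait, is a caller-side
reshaping of the same function).

## Variant-to-gene mapping

Sentinels are expanded to LD proxies and filtered at $r^2 \ge 0.8$; each
sentinel is retained as its own proxy with $r^2 = 1$ (LD is reflexive). The
MHC region defaults to chr6:25,000,000–34,000,000 (GRCh38) and is excluded
because extended LD there defeats proxy assignment; both the window and the
threshold are arguments. A proxy inside a cRE yields one pair per contacted
gene; pairs are deduplicated on (trait, proxy, cell type, gene) with the
union of supporting cRE and loop ids retained. Proxies that fall only in
promoter-overlapping OCRs without loops are *not* V2G hits under the default
contact-based definition. Fine-mapped credible-set variants can be ingested
through the same proxy schema with $r^2$ recorded as 1.

Sharing is evaluated on distinct label sets, ignoring row multiplicity: an
entity (variant, gene, or variant–gene pair) is trait-shared when it occurs
with two or more distinct traits anywhere in the table, cell-shared
analogously, giving the four-way taxonomy. Display percentages round half
away from zero; full-precision values are kept alongside because published
tables sometimes truncate instead.

Precision–recall against a gold-standard list compares upper-cased symbols
with optional alias mapping; precision is the fraction of predicted genes in
the truth set, recall the fraction of the truth set predicted.

## Locus construction and colocalization

Per sentinel, a candidate region is the union of the sentinel position, its
proxy span, and the span extended ±250 kb; overlapping candidates merge.
A merged region with several sentinels stays merged only when the sentinels
form one connected component at pairwise $r^2 \ge 0.8$; otherwise it is cut
at the midpoint between adjacent components' proxy spans. The midpoint rule
is this package's choice where the procedure it follows says only that
low-LD groups are "separated"; it guarantees pairwise non-overlapping output
and is recorded in each locus's provenance field. Splitting necessarily
truncates the ±250 kb windows of the separated groups, so the
window-containment property holds only for unsplit loci.

eGene extraction keeps a gene for a locus when at least one of its eQTL
variants lies in the locus, passes FDR ≤ 0.05, is optionally one of the
locus's high-LD proxies, and the gene is on the locus chromosome. The
significance direction is implemented as FDR ≤ 0.05; a `fdr_rule = "literal"`
flag preserves the opposite reading for auditability. When only p-values are
supplied, Benjamini–Hochberg correction is applied per dataset/cell-type
stratum.

Colocalization follows the single-causal approximate-Bayes-factor model.
Per SNP, with $V = se^2$, $z = \beta/se$ and prior effect variance $W$
($0.2^2$ for case-control, $0.15^2$ for quantitative traits — the
conventional defaults, not MAF-adjusted),

$$\log ABF = \tfrac12\big(\log(1 - r) + z^2 r\big), \qquad r = W/(V+W).$$

Hypothesis sums are assembled entirely in log space with logsumexp; the
distinct-causal sum $\sum_{i \ne j} ABF_{1i} ABF_{2j}$ is computed as a
stable log-difference
$\log(\sum_i ABF_{1i} \sum_j ABF_{2j} - \sum_i ABF_{1i}ABF_{2i})$, which
makes PP.H3 exactly zero for a single shared SNP. Posteriors are the softmax
over $\{0, S_1, S_2, S_3, S_4\}$ and per-SNP PP.H4 the softmax of
$l_1 + l_2$ over SNPs. One correction to a tempting invariance claim:
scaling one dataset's $\beta$ and $SE$ jointly leaves $z$ unchanged but
*changes* the posterior under fixed $W$, because $V$ enters $r$; exact
invariance is a units change, i.e. rescaling $W$ by the same factor squared.
The test-suite checks the exact units form. Multi-causal fine-mapping
(SuSiE-style) is out of scope.

## Motif disruption

Position frequency matrices get a total pseudocount of 0.8 per position
(+0.2 per cell) before row normalization, avoiding $-\infty$ scores.
Sequences score as information content, $\sum_l \log_2(p_{l,b}/bkg_b)$, with
an even background (0.25 per base). The p-value of a score is the exact
upper tail of the score of a background-drawn sequence, obtained by
position-wise convolution of the four-point per-column distributions: exact
value-merging convolution when the outcome space is small ($4^L \le 2^{16}$,
motifs up to 8 bp), and an integer-binned convolution at 10,000 bins across
the score range for longer motifs, whose tie tolerance scales with the bin
width. A variant scan slides the motif over every window covering the
variant on both strands (reverse complement on the minus strand) and reports
windows where the more significant allele passes $p \le 5\times10^{-4}$
(a `require_both` flag demands both alleles pass). Disruption strength
classifies $\Delta = score_{alt} - score_{ref}$ at 1 bit (strong) and 0.4
bits (weak) — the convention of the established motif-disruption tooling,
exposed as arguments since the procedure itself fixes no cutoff.

## The synthetic-data generator

The generator emulates the *downstream products* of the real assays — peak
sets, promoter-anchored loop sets, sentinel/proxy structure with LD, and
locus-level paired summary statistics — not reads, allele frequencies or
population structure. Every feature is placed on a lattice of disjoint
2.5 kb slots: genes (TSS positioned so the promoter window stays inside its
slot), distal OCRs, negative-control loop anchors and free-standing variants
each own a slot, so no overlap exists unless planted. Planted loops connect
a distal OCR's exact interval to a target promoter window, with the target
promoter forced open in that cell type. This makes the planted truth exactly
recoverable: on noiseless defaults the cRE caller returns precisely the
planted contacts and the V2G map equals the planted pair table, which is
what the end-to-end tests assert. The trade-off is explicit: passing these
tests demonstrates correctness of the mapping logic, not robustness to the
partial overlaps, fragment-boundary effects and annotation noise of real
data.

Default study conditions: 2 chromosomes × 10 Mb, 300 genes, 4 cell types ×
~2,000 peaks, 15% of peaks looped to promoters, 3 traits × 20 sentinels,
5–30 proxies per sentinel with $r^2$ straddling 0.8 (sub-threshold proxies
are negative controls), 30% of proxies placed inside cREs, 20% of in-cRE
proxies replicated into a second trait, and loci of 200 SNPs at
$n = 10{,}000$ per study with causal $|z| \approx 8$.

LD inside a locus is a rank-distance AR(1) correlation
($\rho^{|i-j|}$, $\rho = 0.95$) rather than a coalescent simulation — enough
to exercise the $r^2$ threshold and colocalization while keeping desk-scale
runtime. Marginal z-scores are the LD-weighted causal signal plus noise
drawn from $MVN(0, C)$: correlated noise is what the single-causal model
implies, and with independent noise the shared- and distinct-causal
configurations would not be reliably separable at any effect size. Shared
(H4) loci use one causal SNP for both studies; distinct (H3) loci place
causal SNPs at the block's quarter points, where $\rho^{m/2}$ makes their LD
negligible; null loci carry no signal. Under these conditions shared-causal
loci reach PP.H4 ≥ 0.8 and distinct-causal loci PP.H3 ≥ 0.8 in well over
90% of seeded replicates.

Determinism: every generator function seeds R's Mersenne–Twister explicitly
(with fixed normal and sample kinds) from `seed` plus a per-stage offset, so
identical configurations give byte-identical files on any platform.

## Problem sizes and runtime

The test-suite and the acceptance script run at the generator defaults:
full pipeline in seconds, 100-replicate colocalization calibration and the
1,000-configuration locus property in about a minute each, chosen so the
complete suite finishes in a few minutes on one core. These sizes are the
package's own study conditions; the same code runs unchanged at larger
configurations.

## Known limitations

* Loops arrive pre-merged; the resolution-preference merging of overlapping
  multi-resolution loop calls is upstream and out of scope, as are CHiCAGO
  score filtering, liftover and read-level processing.
* The LDSC regression, LD-score computation and baseline-model management
  are external; only `.annot` construction and `.results` post-processing
  live here.
* Single-causal colocalization only; loci with several causal variants per
  study need a multi-causal method.
* The generator's planted LD ($r^2$ values, sentinel LD matrix) is drawn,
  not derived from genotypes; it exercises thresholds, not population
  genetics.
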