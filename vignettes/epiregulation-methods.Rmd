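---
title: "Methods: differential methylation, epiregulation screening and PNPF statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation, epiregulation screening and PNPF statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`epiregseek` re-implements, as a tested pipeline, an integrated analysis
of how temperature and photoperiod reshape a plant shoot-apex methylome
and transcriptome, and of how those molecular changes relate to the
seasonal instability of cucumber sex expression. This vignette is the
package's own account of the models and procedures, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the underlying methods left choices
open.

## The experimental design being modelled

Four incubator conditions cross two temperatures with two photoperiods:
LS (low temperature, short day), LL (low/long), HS (high/short), HL
(high/long). LS serves as the control throughout. For each condition the
design provides one pooled whole-genome bisulfite (WGBS) library — shoot
apices are pooled before sequencing, so the methylome has **no
biological replicates** — and three RNA-seq replicates. Alongside the
incubator experiment stands a germplasm field survey: 359 cucumber
accessions scored in spring and early autumn over five consecutive years
(three replicate plots per accession-year-season) for PNPF, the
proportion of the first 25 main-stem nodes bearing pistillate (female)
flowers.

## Methylome analysis

**Contexts.** Plant cytosine methylation is classified 5'→3' on the
cytosine's own strand into CG, CHG and CHH (H = A, T or C).
Classification needs the two downstream bases; sites truncated by the
chromosome end or containing N are left unclassified. CG sites are kept
strand-specific — symmetric CpG pairs are *not* merged — so every
count and every intersection key is a single cytosine on a single
strand.

**Methylcytosine calling.** With bisulfite conversion rate $c$, an
unmethylated cytosine still yields a methylated read with probability
$1-c$. A site with $n$ reads is called methylated only when its
methylated-read count reaches the smallest $k$ with
$P(X \ge k \mid X \sim \mathrm{Bin}(n, 1-c)) < \alpha$. The tail
threshold $\alpha$ defaults to 0.05 and is configurable, since the
source procedure names the binomial construction but not its level; no
multiple-testing adjustment is applied to mC calls.

**Differential cytosines (DmCs).** Each site covered in both samples is
tested with a two-sided Fisher exact test on the 2×2
methylated/unmethylated table; a DmC needs $p < 0.05$ *and* a
methylation-level change of at least 20 percentage points. The change
threshold is read as an absolute difference $|ML_B - ML_A| \ge 0.2$, the
standard WGBS usage — a relative reading is unstable near zero.
Deliberately, *no* FDR correction is applied to DmC p-values: the
procedure being reproduced states raw $p < 0.05$ plus the delta filter.
Sites with fewer than 4 reads in either sample are excluded from
testing by default (Fisher on tiny counts has essentially no power);
the floor is configurable down to 1. The Fisher p-value is computed
in-package as a vectorised hypergeometric tail sum — `fisher.test` is
used as the independent oracle in the test suite but is far too slow to
call hundreds of thousands of times.

**DMR calling (seed and extend).** Within one context, the testable
sites of a chromosome (both strands pooled in coordinate order — the
natural reading of "adjacent motifs" along the chromosome; a
strand-separated mode exists) are scanned in 5-site windows. A window
seeds a region when at least four of its five sites are DmCs sharing one
direction and a two-sided Wilcoxon rank-sum test comparing the five
per-site methylation levels between samples gives $p < 0.05$. By default
an opposite-direction DmC anywhere in the window vetoes the seed; a flag
relaxes this, since "five adjacent motifs containing at least four with
the same response pattern" does not say whether the fifth may respond
oppositely. Seeds are extended site by site toward increasing
coordinates ("3' downstream" is read relative to the chromosome, the
only orientation available once strands are pooled): a site joins if it
is a DmC of the seed's direction (a lenient mode also admits
non-significant sites whose difference has the right sign) and the
rank-sum test over the enlarged sets stays below 0.05; the first failure
ends the region. Overlapping same-direction candidates are merged and
their statistics recomputed over the union of member sites. Finally,
candidates spanning less than 50 bp or with a mean methylation-level
difference below 0.1 are discarded; both thresholds are inclusive
because the rule discards regions *strictly smaller* than the cutoffs.

The rank-sum p-value is exact — an exhaustive enumeration over all
$\binom{n_1+n_2}{n_1}$ labelings of the pooled mid-ranks, which handles
ties correctly as a permutation test — whenever both groups have at
most 8 values, and a tie-corrected normal approximation with continuity
correction beyond that. The exact small-sample branch matters: the seed
test always compares 5 against 5, where the smallest attainable
two-sided p is $2/252 \approx 0.0079$.

**Summaries.** Per-context mean methylation level is averaged over
covered sites only (zero-coverage sites are undefined, not zero); mC/C
is the called-mC fraction of covered cytosines; treatment effects are
reported as increment rates $(t - c)/c$ relative to the control.

## Feature association

A genic region is the gene body plus 2 kb on both sides, clipped to the
chromosome. A point query (a DmC, or the midpoint of a DMR or DET) may
lie in several features at once: TE membership is overlap with the TE
body; genic membership is overlap with any genic region; a genic point
is then assigned to the single nearest gene, with distance measured to
the gene *body* (0 inside) — the source says only "nearest genes", and a
TSS-distance mode is provided — and exact ties broken toward the
lexicographically smaller gene id so the assignment is deterministic.
The four reported categories are gene-only, TE-only, TE&gene, and none.
DMR–TE association, by contrast, uses interval overlap of the whole DMR
with the TE body, exactly as the two rules are stated separately in the
source procedure. Shared DmCs across treatment comparisons are keyed by
(chromosome, position, strand, context); their per-comparison deltas
give a sign-concordance fraction. Chromosome-scale distributions use
half-open fixed windows (2 Mb at genome scale; the bundled analyses bin
the short simulated chromosomes at 50 kb).

## Expression and the epiregulation screen

**DEGs.** Differential expression between two conditions uses a
divergence probability in the spirit of noise-distribution ("NOISeq
style") screens, re-implemented so the pipeline is self-contained: the
signal for a gene is the pair $(|M|, |D|)$ of the log2 ratio and the
absolute difference of its two condition means (both FPKM + 1); the
noise cloud pools the same statistics over every within-condition
replicate pair of every gene; the probability is the fraction of noise
points strictly dominated in both coordinates. A DEG needs probability
≥ 0.8 and fold-change ≥ 2 on the pseudocounted means. An import path
accepts externally computed probabilities. The pseudocount (1 FPKM)
stabilises zeros, which would otherwise give infinite fold-changes.

**Per-gene ANOVA.** The 2×2×3 design admits a closed-form balanced
two-way fixed-effects decomposition of log2(FPKM + 1), vectorised
across genes (all classical SS types coincide on a balanced design);
the test suite checks the closed form against `aov` gene by gene.

**DETs.** TE expression is normalised as
FPKM = count / (length/10³) / (library/10⁶) with the library equal to
total aligned fragments. TEs overlapping any protein-coding gene body
are discarded before testing. The differential test is edgeR's exact
negative-binomial test on the replicate counts (library sizes as given,
no extra scaling normalisation), followed by Benjamini–Hochberg
adjustment and an adjusted-p < 0.05 cutoff. The source names only
"adjusted p-values"; a pooled-count conditional binomial was tried
first and found badly anticonservative under replicate overdispersion,
so the standard replicate-aware NB test is used instead.

**Epiregulation.** Only CG- and CHG-context DMRs are eligible (CHH
regions are filtered, not an error). A DMR associates with a gene when
its midpoint falls in a CDS interval or within 2 kb (inclusive) of the
TSS or TES, the mRNA boundaries. Each association joins the gene's DEG
record for the same ordered condition change; the sign is positive when
methylation and expression move together (hyper with up, hypo with
down) and negative otherwise. Positive associations are discarded and
the genes of the remaining negative associations, deduplicated, form
the putative epiregulated list. Both directions use the same
treatment-minus-control orientation, so the sign convention is fixed by
the ordered condition pair.

## PNPF phenotype statistics

PNPF is the pistillate fraction of the first 25 main-stem nodes. Spring
PNPF classifies accessions into subandroecy (< 25%), normal monoecy
(25% ≤ PNPF < 75%) and gynoecy/subgynoecy (≥ 75%); both boundaries are
lower-inclusive, as the class definitions state them. All parametric
statistics run on arcsine-transformed values, $\arcsin\sqrt{p}$.

Per-accession seasonal change uses a two-sample t-test (Welch by
default; a pooled-variance flag exists since the source says only
"t-test") on the transformed spring versus early-autumn values;
accessions with fewer than two observations per season *or a constant
response* — notably subandroecy lines clamped near zero — are flagged
not testable rather than tested. Summary counts report accessions with
a significant decrease and with a relative decrease beyond 40%, plus
the linear fit of autumn on spring means.

The field survey is decomposed by a fixed-effects nested ANOVA — Year,
Variety, Season(Year), Year×Variety, Season(Year)×Variety, Residual —
with the classical df formulas (for 5 years, 2 seasons, 359 varieties:
4, 358, 5, 1432, 1790). The sums of squares are computed directly from
balanced group means rather than through a linear-model fit: the full
design has ~3,600 coefficients and 10,770 rows, which a dense QR cannot
handle, while the balanced decomposition is exact and instantaneous
(and is verified against `aov` on small designs in the tests). The
incubator experiment gets the full three-way variety × temperature ×
photoperiod decomposition via `aov`. All F statistics use the residual
mean square as denominator — the fixed-effects reading implied by the
published significance stars; mixed-model denominators are out of
scope. `finalize_table()` fills MS = SS/df and TSS% = 100·SS/total at
the published tables' printed precision (MS to 3 decimals; TSS% to 2
for the field survey, 3 for the incubator table), which is how the
worked-example cells of the published ANOVA skeletons are recomputed.
Two published arithmetic quirks are noted and left alone: a couple of
MS cells disagree with their own printed SS/df at the last digit
(upstream rounding), and the incubator table prints total df = 48 where
the data imply 47; the package reports n − 1.

## The synthetic-data generator

Every stage above is exercised on data from `simulate_study()`, which
plants known truth and makes it recoverable:

* **Genome**: i.i.d. bases at GC 0.37 (plant-like), default 2 × 400 kb
  — large enough to hold a 100-gene, 80-TE annotation with 2-kb flanks
  and dense cytosine series, small enough that the whole pipeline runs
  in seconds.
* **Annotation**: non-overlapping gene models (bodies 1.5–3.5 kb, 2–4
  CDS exons, random strand) in evenly spaced slots; TEs (0.3–2 kb) with
  an LTR-dominated class mix, a configurable fraction overlapping genic
  regions.
* **Methylome**: per-site true methylation drawn from a Beta around the
  context baselines CG 0.80 / CHG 0.55 / CHH 0.10 (typical plant
  levels); coverage negative-binomial (mean 30, size 10 — WGBS is
  overdispersed, and this stresses the coverage floor); conversion rate
  0.99, so unmethylated cytosines read methylated at 1%. Planted DMRs
  are 150-bp intervals holding ≥ 8 same-context cytosines (placement
  retries until that holds, so recovery is well posed), |ΔML| = 0.8
  for background regions, 70% hypermethylated — high temperature and
  long days predominantly hypermethylate — with half the regions
  planted identically in LL, HS and HL so they are *shared* relative to
  LS; promoter coupling regions use |ΔML| = 0.5.
* **Expression**: NB counts (size 300, ~6–8% replicate CV, matching the
  tight replicate clustering the source reports) around log-normal
  baselines (meanlog 4.3, sdlog 1); planted DEGs at |log2FC| = 3 as
  baseline-matched up/down pairs, planted couplings at |log2FC| = 2
  (down for negative couplings, up for the positive controls). Library
  sizes include a large simulated background mass (10⁶ fragments) so
  the small panel behaves like a genome-scale library: without it, the
  planted fold-changes themselves shift every gene's FPKM through the
  denominator — a compositional artifact real 23k-gene transcriptomes
  do not show. Planted features are drawn from a moderate abundance
  band (≥ 75 baseline counts, ≤ 90th percentile): real condition-
  responsive DEGs are expressed genes, and the divergence-probability
  statistic is structurally blind to shifts whose absolute difference
  cannot clear the noise tail of the most abundant genes.
* **Phenotype**: generated on the arcsine scale — grand mean
  asin√0.35, normal effects from the configured variance components,
  a fixed 0.25 early-autumn drop for the 90% of accessions marked
  season-sensitive — then back-transformed, so the ANOVA assumptions
  hold exactly on the analysis scale. The design (359 × 5 × 2 × 3)
  reproduces the published degrees of freedom.

All draws flow from one seed via fixed per-stage offsets, so identical
configurations give byte-identical outputs.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: no read-level artifacts (M-bias,
mapping bias, PCR duplicates), no chromatin-scale methylation
autocorrelation outside planted regions (background sites are
independent), no partially methylated domains, no TE-family sequence
homology, no expression–methylation coupling other than the planted
one, and seasonal phenotype effects that are exactly additive on the
arcsine scale. Recovery rates on this generator certify the
implementation, not the biology.

## Numerical choices and degenerate inputs

Zero-coverage sites have undefined (not zero) methylation level and are
excluded from summaries and tests. Fisher p-values use the same
`1 + 10^-7` relative tolerance as the reference implementation when
summing tail tables. The exact Wilcoxon branch bounds both groups at 8;
at the 5-vs-5 seed size enumeration costs 252 labelings. Empty
extension returns the seed span; an all-identical window returns p = 1.
DMR ids are assigned after sorting by (chromosome, start), so output
order is deterministic. `min_meth_reads` returns a no-call marker at
zero coverage or when even all-methylated coverage cannot clear the
tail. Interval arithmetic is 1-based inclusive throughout the R API
(files follow their formats: GFF3 and the cytosine reports 1-based, BED
0-based half-open); window binning is half-open so a feature exactly at
a boundary belongs to the following window.

## Problem sizes

The bundled analyses and the acceptance script run the default study:
an 800-kb genome (~300k classifiable cytosines), four WGBS conditions
at 30× mean coverage, 12 RNA-seq samples over 100 genes and 80 TEs, and
the 10,770-row germplasm table. A full run of every stage takes on the
order of a minute; the region-recovery study (24 planted regions, three
condition pairs) is the slowest single step. These sizes were chosen so
that each recovery statistic rests on enough planted instances to be
stable across seeds while the whole suite stays interactive.

## Known limitations

The divergence probability is a documented approximation of the named
package's statistic, not a re-implementation of it; headline counts
from the original genome-scale study (half-million DmC totals, 537
DEGs, 239 association events) require the original sequencing libraries
and tool versions and are out of scope — the pipeline's claims are the
procedure definitions plus parameter recovery on planted truth. The mC
caller assumes a single genome-wide conversion rate rather than
estimating it from a spike-in. The DMR caller is the seed-and-extend
procedure by construction; it is not an HMM or smoothing caller and
inherits the known behaviour of such scanners (regions can truncate at
sparse or low-coverage stretches). Mixed-model variance components for
the phenotype tables are intentionally not estimated.
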