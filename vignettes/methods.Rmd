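---
title: "Models and methods behind mesohet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mesohet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesohet)
```

`mesohet` quantifies intra-tumor heterogeneity between two biopsies of the
same tumor taken at different anatomical sites. This vignette explains the
statistical models, the tunable parameters, and the design decisions made
where more than one reasonable choice existed.

## Cancer cell fraction and clonality

A somatic variant observed at allele frequency $v = $ alt reads / depth in
a biopsy of tumor purity $p$ lies on a locus of tumor copy number $C_t$
(normal copy number $C_n = 2$). Assuming every tumor cell carrying the
variant carries it on $m$ copies, the expected VAF of a variant present in
a fraction $f$ of tumor cells (the cancer cell fraction, CCF) is

$$ E[v] = \frac{f \, m \, p}{p\,C_t + (1-p)\,C_n}, $$

which inverts to $f = v\,(p C_t + (1-p) C_n)/(p\,m)$. `estimate_ccf()`
estimates the multiplicity as the nearest integer of the uncorrected value
clamped to $[1, \text{major CN}]$ — with no segment information $m = 1$ and
$C_t = 2$. This is the standard purity/ploidy correction used by
CCF-estimation tools; we make no claim of numerical identity with any
particular implementation.

**Confidence intervals.** The binomial uncertainty on $v$ dominates at
exome depths, so the 95% interval is an exact Clopper–Pearson interval on
$v$ (via the beta quantile identity) pushed through the same linear
transform. The exact interval is conservative (coverage $\ge$ the nominal
level), which fits its role here: the subclonality rule requires the upper
bound to fall *below* 1, so conservatism errs toward calling variants
clonal rather than inventing subclones.

**Classification.** Across a pair, a variant is *shared* when observed in
both biopsies, else *private*. It is *subclonal* when CCF < 0.5 and the
upper CI bound < 1 — required in **both** samples for shared variants. The
threshold 0.5 and the CI rule are taken literally and strictly; CCF
exactly 0.5 is clonal. The source description of the CI rule does not say
whether one or both samples must satisfy it; we require both, the
conservative reading, since a single noisy sample should not demote a
clonal variant. For private variants the same two conditions apply to the
single observed sample.

**Copy-number events** get CCF = cellular fraction / purity (no CI rule).
Quotients above 1.1 warn (purity misestimation) and cap at 1. Segments are
matched across the pair when they share the chromosome, the state class
(gain / loss / copy-neutral LOH) and overlap reciprocally by ≥ 50%; no
published matching rule existed to follow, and reciprocal overlap is the
usual interval-matching criterion in CNV comparison. Homozygous deletions
are reported separately rather than matched, since their cellular fraction
is rarely reliable.

**Shared subclones.** `detect_shared_subclone()` flags a pair when at
least 2 variants are subclonal-shared. One variant is too fragile a basis
for claiming polyclonal dissemination (a single borderline CCF can cross
0.5 by sampling noise); the motivating observation had six supporting
variants, so 2 is a deliberately permissive default that still requires
corroboration.

**CCF cap.** Estimates are capped at 1.5 (configurable) and flagged, never
silently renormalized to 1: over-unity CCFs are a diagnostic for purity or
copy-number misestimation and should remain visible.

## Paired expression rules

Differential expression between two biopsies of one patient cannot use
replicate-based machinery, so the caller is rule-based: genes with
FPKM < 1 in both biopsies are excluded, and a gene is DE when the absolute
difference of variance-stabilized values exceeds 1 (strictly). On the VST
(log2-like) scale a difference of 1 is roughly a two-fold change. The
"most variable" genes for clustering are ranked by per-gene range across
the cohort (configurable to variance); range is the natural reading for
small cohorts where a single divergent pair should promote a gene.

Clustering uses cosine distance ($1 - $ cosine similarity) with Ward
linkage, implemented as `stats::hclust(method = "ward.D2")` on the
distance matrix; `ward.D2` is the variant consistent with Ward's
minimum-variance criterion for a distance input. Zero-norm samples have no
direction and are an error, not a silent drop.

**E/S deconvolution.** The histo-molecular composition of MPM is modeled
as a two-component mixture of an epithelioid-like and a sarcomatoid-like
reference profile. `deconvolve_es()` solves
$\min_w \|x - (w E + (1-w) S)\|^2$ on the simplex, which for two
components has the closed form $w = \langle x - S, E - S\rangle /
\|E-S\|^2$ clipped to $[0,1]$. This is an acknowledged simplification of
richer published deconvolution approaches (which add marker selection and
uncertainty estimation); for two fixed profiles the least-squares simplex
solution is exact and deterministic. Collinear profiles (r > 0.999) are
rejected since the mixture is then unidentifiable. A pair is heterogeneous
when the E score changes by strictly more than 0.10 (a comparison at the
threshold is guarded against floating-point round-off at 1e-9).

## Methylation rules

A CpG is DM when both detection p-values are < 0.05 and the beta
difference is at least 0.2 (inclusive — note the deliberate asymmetry with
the strict DE rule; both thresholds are taken literally from their
definitions). The DE_DM set intersects DE genes with genes holding ≥ 1 DM
CpG via the annotation table; the direction-consistency filter keeps a
DE_DM gene only when its expression change matches the sign expected from
the E-score change (genes positively correlated with E must follow the E
delta, genes positively correlated with S must oppose it). Methylation
direction (hyper/hypo) is reported but not used by the filter, which is
defined on expression changes only. Genes absent from the correlation
table are counted outside the denominator rather than dropped silently.

## Pathway scoring

Over-representation uses the hypergeometric upper tail
$P[X \ge k]$ for overlap $k$ between the query and a set intersected with
the universe, BH adjustment within each collection, significance at
FDR < 0.05, and gene ratio = overlap / set size. The background universe
is the expression universe after filtering, not the genome: queries are DE
gene lists, and only measured genes could have entered them.

Single-sample GSEA follows the rank-weighted ECDF construction: within a
sample, genes are ranked by expression, and a set's score is the summed
difference between the weighted (rank$^{\alpha}$, $\alpha = 0.25$) CDF of
in-set genes and the unweighted CDF of out-of-set genes, with genes at
FPKM < 1 in all samples removed beforehand and final scores rescaled by
the global score range. $\alpha = 0.25$ and range normalization are the
conventional single-sample defaults. A set with no expressed member is
undefined (`NA`), never zero — zero is a meaningful score. Pathway-level
heterogeneity of a pair is the absolute score difference per set.

## Microenvironment

Population scores are MCP-counter-style: the mean log2-scale expression of
the population's marker genes. Markers are first refined against a panel
of tumor cell lines — a marker expressed (FPKM ≥ 1) in any line is removed,
so scores track infiltrating cells rather than the malignant compartment.
The threshold 1 is the same "expressed" floor used elsewhere in the
package; no published value existed to adopt. For cross-dataset
integration every row is z-standardized within each dataset using the
population (denominator $n$) standard deviation, which makes the transform
idempotent — re-standardizing changes nothing beyond 1e-12, a property the
tests assert. Hot/cold status is a $k=2$ cosine/Ward cut with the
higher-grand-mean cluster labeled hot; patients with one hot and one cold
biopsy are flagged mixed. Paired population differences use the exact
Wilcoxon signed-rank null for ≤ 25 populations. Checkpoint genes are
flagged at fold change ≥ 2 among genes with FPKM > 1 in at least one
biopsy; the denominator of the fold change is floored at 0.1 so a zero
FPKM cannot divide by zero while leaving ordinary ratios untouched.

## The synthetic cohort generator

`simulate_clone_structure()` draws a trunk plus subclones descending from
it, with per-site exclusive clone fractions; the true CCF of a mutation at
a site is exactly the sum of the fractions of clones carrying it, and
trunk mutations have CCF 1 everywhere. Scenarios fix the spatial pattern:
`shared_subclone` keeps every subclone in (0, 0.5) at both sites (the
polyclonal-dissemination configuration), `private_subclones` confines each
subclone to one site, and `mixed` draws both kinds, letting private clones
reach fractions up to 0.85 so that clonal-private ground truth also
occurs.

Reads follow the same binomial model the estimator inverts: depth is
Poisson around the mean (floored at 20 to avoid degenerate intervals —
no sequencing-noise model was available to reproduce, so this is a
calibration choice), and a variant drawing zero alt reads is emitted as
absent, the simplest detection model consistent with how callers behave.
Expression is built additively on the VST scale from the E/S mixture,
immune components over marker genes, planted DE shifts and Gaussian noise,
with FPKM linked as $2^v - 1$ so the FPKM < 1 filter coincides with
VST < 1. Methylation draws bimodal Beta baselines (mostly-unmethylated or
mostly-methylated CpGs, as on arrays) and shifts planted DM CpGs toward
the free end of $[0,1]$ so clipping cannot shrink the planted difference.
Purities default to Uniform(0.3, 0.9), the realistic spread for surgical
biopsies of this tumor; recovery experiments restrict to ≥ 0.5 because
low-purity samples are exactly where clonality analysis degrades.

What the generator does **not** emulate: sequencing artifacts and strand
bias, subclonal copy-number structure interacting with multiplicity,
FFPE damage, array normalization effects, and realistic gene–gene
correlation in expression. Passing recovery tests therefore demonstrate
the correctness and calibration of the estimators under their own model
assumptions — not performance on real tumors, where purity estimation and
copy-number calls add errors upstream of this package.

## Problem sizes and numerical choices

Recovery experiments use 100 replicate tumors of 200 variants at depth
500, interval coverage 5,000 variants at depth 100, and deconvolution /
hot-cold checks 100 replicates each — sizes at which the binomial Monte
Carlo error of the measured rates is well below the margins being
asserted, while a full run stays in the minutes range on one CPU. Ties in
variable-feature selection and centroid correlation break
lexicographically (deterministically); inclusive/strict threshold
comparisons at exact boundary values are guarded at 1e-9; the pipeline
writes no timestamps, so identical configs reproduce byte-identical
outputs, which the test suite asserts.

## Known limitations

- CCF estimation assumes the supplied purity and copy-number segments are
  correct; their errors propagate undiagnosed (beyond the over-unity CCF
  flag).
- The two-profile E/S deconvolution cannot express a third expression
  program; residual norm is not currently reported.
- ssGSEA scores are comparable only within this implementation; no
  numeric identity with other GSEA software is claimed.
- The pipeline enforces exactly two tumor samples per patient;
  `select_closest_purity_pair()` is provided for pre-selecting among more.
- Hot/cold assignment is a relative, cohort-dependent 2-cluster call: the
  same sample can switch labels in a different cohort composition.
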