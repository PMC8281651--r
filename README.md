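# mesohet

Multi-site intra-tumor heterogeneity analysis for malignant pleural
mesothelioma (MPM) and similar diffusely growing tumors sampled at several
anatomical sites.

MPM grows as a sheet across the pleural cavity, and a single biopsy can
misrepresent the tumor's genetics, transcriptome and immune contexture.
`mesohet` is for cancer genomics analysts working with paired biopsies of
the same tumor (e.g. apex vs costo-diaphragmatic sites): it quantifies how
much the two samples disagree at every molecular layer, and whether the
disagreement is consistent with multiple tumor subclones spreading jointly
through the cavity (polyclonal dissemination).

## What it computes

**Clonality.** For a variant with allele frequency VAF in a biopsy of
purity *p*, local tumor copy number *C_t* and normal copy number *C_n*, the
cancer cell fraction is

    CCF = VAF * (p * C_t + (1 - p) * C_n) / (p * m)

with multiplicity *m* the nearest integer of the uncorrected value clamped
to [1, major copy number]. 95% intervals come from an exact Clopper–Pearson
interval on the VAF pushed through the same transform. Across a biopsy
pair, every variant is classified **clonal/subclonal x shared/private**: a
variant is subclonal only when CCF < 0.5 with the upper CI bound < 1 (in
both samples when shared), and shared when observed in both biopsies.
Copy-number events use CCF = cellular fraction / purity with no CI rule.
Two or more shared subclonal variants raise the polyclonal-dissemination
flag. A schematic clonal tree summarizes the categories.

**Expression.** Paired differential expression by rule: exclude genes with
FPKM < 1 in both biopsies, call DE when the variance-stabilized (VST)
difference exceeds 1. Epithelioid/sarcomatoid composition (E.score +
S.score = 1) is estimated by simplex-constrained least squares against two
reference profiles; an E/S change > 10% flags histo-molecular
heterogeneity. Molecular subtypes come from nearest-centroid (Pearson)
classification, cohort structure from cosine-distance/Ward clustering of
the 500 most variable genes.

**Methylation.** A CpG is differentially methylated (DM) when both
detection p-values are < 0.05 and the beta-value difference is >= 0.2.
DE genes with >= 1 DM CpG form the DE_DM set, optionally filtered for
direction consistency with the E/S gradient.

**Pathways.** Over-representation by hypergeometric test with
Benjamini–Hochberg FDR (< 0.05) and gene ratios; single-sample GSEA
(rank-weighted ECDF, alpha = 0.25) with the absolute paired score delta as
the heterogeneity measure.

**Microenvironment.** MCP-counter-style scores (mean log2 expression of
population markers, after removing markers expressed by tumor cell lines),
per-dataset z-standardization, hot/cold assignment by 2-group clustering,
paired Wilcoxon tests and an immune-checkpoint fold-change rule
(FC >= 2 among genes with FPKM > 1 in at least one biopsy).

A synthetic cohort generator (`simulate_cohort()`) produces two-biopsy
tumors with known clone trees, planted DE genes, DM CpGs, E/S mixtures and
immune components, so the whole stack is testable without controlled-access
patient data.

## Worked example

```r
library(mesohet)

# a tumor with a trunk plus one 6-variant subclone present in both biopsies
cs <- simulate_clone_structure(n_trunk_mut = 10, n_subclones = 1,
                               muts_per_subclone = 6,
                               scenario = "shared_subclone", seed = 7,
                               purity = c(0.8, 0.8))
rd <- simulate_variant_reads(cs, mean_depth = 600, seed = 7)
calls <- pair_clonality(rd$A, rd$B, 0.8, 0.8)
table(calls$category)
#>    clonal_shared subclonal_shared
#>               10                6

detect_shared_subclone(calls)$flag
#> [1] TRUE

build_clonal_tree(calls)
#> Clonal tree with 2 node(s)
#>   trunk              parent=-                sites=AB  n=10
#>   shared_subclone    parent=trunk            sites=AB  n=6
```

The ten trunk variants are clonal in both biopsies (CCF ~= 1); the six
subclone variants sit below CCF 0.5 in *both* sites, which is what flags
possible polyclonal dissemination. An end-to-end run over a full cohort:

```r
co <- simulate_cohort(n_patients = 8, mixed_pair_patient = 3, seed = 5)
dir <- tempfile(); write_cohort(co, dir, seed = 5)
reports <- run_pipeline(file.path(dir, "config.yaml"))
reports$P03$microenvironment$mixed_pair
#> [1] TRUE   # the planted hot/cold discordant patient
```

Each patient's `report.json`, plus per-stage TSVs (clonality calls, DE/DM
tables, ORA results, ssGSEA scores, hot/cold labels), lands under the
configured output directory. A thin CLI wrapper is available as
`exec/mesohet` (`mesohet simulate`, `mesohet run-all`).

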