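Package: mesohet
Title: Multi-Site Intra-Tumor Heterogeneity Analysis for Pleural Mesothelioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify intra-tumor heterogeneity from paired biopsies
    of malignant pleural mesothelioma profiled at multiple anatomical sites.
    Implements per-variant cancer-cell-fraction (CCF) estimation with exact
    binomial confidence intervals, clonal/subclonal by shared/private
    classification of variants and copy-number segments across a biopsy pair,
    detection of shared subclonal populations (a polyclonal-dissemination
    signal), paired differential-expression and differential-methylation
    calling with rule-based thresholds, epithelioid/sarcomatoid (E/S)
    histo-molecular score deconvolution, pathway over-representation and
    single-sample GSEA delta scoring, and MCP-counter-style immune
    microenvironment profiling with hot/cold classification. A synthetic
    multi-site cohort generator with known ground truth supports end-to-end
    testing without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
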