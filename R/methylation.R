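#' Call differentially methylated CpGs between paired biopsies
#'
#' A CpG is differentially methylated (DM) when the detection p-value is
#' below 0.05 in both biopsies and the beta-value difference is at least
#' `delta` (inclusive, default 0.2). The direction is that of
#' beta_B - beta_A (hyper = +1 in B relative to A).
#'
#' @param beta_a,beta_b named numeric vectors of beta-values in \[0, 1\].
#' @param p_a,p_b named numeric vectors of detection p-values.
#' @param delta minimum absolute beta difference, met inclusively
#'   (default 0.2).
#' @param p_max detection p-value cutoff, strict (default 0.05).
#' @return data.frame of DM CpGs (`cpg`, `delta_beta` = B - A, `direction`).
#' @export
call_dm_cpg <- function(beta_a, beta_b, p_a, p_b, delta = 0.2, p_max = 0.05) {
  cpg <- names(beta_a)
  if (is.null(cpg)) stop("inputs must be named by CpG id")
  if (!identical(cpg, names(beta_b)) || !identical(cpg, names(p_a)) ||
      !identical(cpg, names(p_b)))
    stop("CpG universes differ between inputs")
  if (any(beta_a < 0 | beta_a > 1 | beta_b < 0 | beta_b > 1, na.rm = TRUE))
    stop("beta-values must lie in [0, 1]")
  db <- beta_b - beta_a
  # inclusive threshold, guarded against floating-point round-off
  dm <- p_a < p_max & p_b < p_max & abs(db) >= delta - 1e-9
  dm[is.na(dm)] <- FALSE
  data.frame(cpg = cpg[dm], delta_beta = db[dm],
             direction = ifelse(db[dm] > 0, "hyper_in_B", "hypo_in_B"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intersect DE genes with DM CpGs
#'
#' A gene is DE_DM when it is differentially expressed and at least one of
#' its annotated CpGs is differentially methylated. The headline percentage
#' is taken over the DE genes considered (protein-coding DE genes when a
#' coding flag is supplied).
#'
#' @param de_genes character vector of DE gene ids.
#' @param dm_cpgs character vector of DM CpG ids.
#' @param annotation data.frame mapping `cpg` to `gene` (many-to-one; CpGs
#'   with `NA` gene are unannotated).
#' @param coding_genes optional character vector restricting the
#'   denominator to protein-coding genes.
#' @return list: `genes` (the DE_DM set), `percentage`
#'   (100 * |DE_DM| / |DE considered|), `n_de` (the denominator).
#' @export
de_dm_genes <- function(de_genes, dm_cpgs, annotation,
                        coding_genes = NULL) {
  de <- if (is.null(coding_genes)) de_genes
        else intersect(de_genes, coding_genes)
  dm_genes <- unique(annotation$gene[annotation$cpg %in% dm_cpgs &
                                       !is.na(annotation$gene)])
  hits <- sort(intersect(de, dm_genes))
  pct <- if (length(de)) 100 * length(hits) / length(de) else 0
  list(genes = hits, percentage = pct, n_de = length(de))
}

#' Filter DE_DM genes for direction consistency with the E/S gradient
#'
#' Keeps a DE_DM gene only when its expression change between the two
#' biopsies points in the direction expected from the histo-molecular
#' gradient: a gene positively correlated with the E score must change with
#' the same sign as the E-score change (A to B), and a gene positively
#' correlated with the S score must change with the opposite sign. Genes
#' absent from the correlation table cannot be evaluated and are reported
#' separately, outside the proportion's denominator.
#'
#' @param de_dm data.frame with columns `gene` and `sign` (sign of
#'   VST_A - VST_B).
#' @param es_table data.frame with columns `gene` and `sign`, the latter in
#'   `c("positive_with_E", "positive_with_S")`.
#' @param es_delta signed E-score change A to B (e_A - e_B); a zero change
#'   makes the filter meaningless and returns an empty set with a warning.
#' @return list: `kept` (consistent genes), `dropped` (inconsistent),
#'   `not_in_table`, `proportion` (consistent / evaluated).
#' @export
direction_consistency_filter <- function(de_dm, es_table, es_delta) {
  if (es_delta == 0) {
    warning("E-score change is zero; direction filter is undefined")
    return(list(kept = character(), dropped = character(),
                not_in_table = de_dm$gene, proportion = NA_real_))
  }
  bad <- setdiff(unique(es_table$sign),
                 c("positive_with_E", "positive_with_S"))
  if (length(bad)) stop("unrecognized correlation sign(s): ",
                        paste(bad, collapse = ", "))
  i <- match(de_dm$gene, es_table$gene)
  evaluable <- !is.na(i)
  # expression change A->B has sign -sign(VST delta is A - B)... the stored
  # sign already is sign(VST_A - VST_B); the E-score delta uses the same
  # orientation, so consistency compares them directly.
  expected <- ifelse(es_table$sign[i[evaluable]] == "positive_with_E",
                     sign(es_delta), -sign(es_delta))
  consistent <- de_dm$sign[evaluable] == expected
  kept <- de_dm$gene[evaluable][consistent]
  dropped <- de_dm$gene[evaluable][!consistent]
  list(kept = kept, dropped = dropped,
       not_in_table = de_dm$gene[!evaluable],
       proportion = if (any(evaluable)) mean(consistent) else NA_real_)
}

#' Select the most variable CpGs across a cohort
#'
#' Ranks CpGs by the range of their beta-values across samples and returns
#' the top `n`, ties broken lexicographically by CpG id; feeds
#' [cosine_ward_cluster()].
#'
#' @param beta CpGs x samples matrix with CpG rownames.
#' @param n number of CpGs (default 500).
#' @return character vector of CpG ids.
#' @export
top_variable_cpg <- function(beta, n = 500) {
  top_variable_genes(beta, n = n, criterion = "range")
}
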