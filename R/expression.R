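#' Call differentially expressed genes between paired biopsies
#'
#' Rule-based paired DE call: a gene is excluded when its FPKM is below 1 in
#' both biopsies; among the remaining genes, a gene is differentially
#' expressed when the absolute difference of its variance-stabilized (VST)
#' values exceeds `delta` (strictly). The sign is that of VST_A - VST_B.
#' Genes with missing values in any input are skipped and counted.
#'
#' @param fpkm_a,fpkm_b named numeric vectors of FPKM per gene for the two
#'   biopsies (same gene universe).
#' @param vst_a,vst_b named numeric vectors of VST values, same genes.
#' @param delta VST difference threshold, exceeded strictly (default 1).
#' @param fpkm_min FPKM floor: genes below it in both biopsies are excluded
#'   (default 1).
#' @return data.frame of DE genes (`gene`, `delta_vst`, `sign`), with
#'   attribute `n_skipped` (genes dropped for missing values).
#' @export
call_de_genes <- function(fpkm_a, fpkm_b, vst_a, vst_b,
                          delta = 1, fpkm_min = 1) {
  genes <- names(vst_a)
  if (is.null(genes)) stop("inputs must be named by gene")
  if (!identical(genes, names(vst_b)) || !identical(genes, names(fpkm_a)) ||
      !identical(genes, names(fpkm_b)))
    stop("gene universes differ between inputs")
  ok <- stats::complete.cases(fpkm_a, fpkm_b, vst_a, vst_b)
  n_skipped <- sum(!ok)
  expressed <- !(fpkm_a < fpkm_min & fpkm_b < fpkm_min)
  dv <- vst_a - vst_b
  de <- ok & expressed & abs(dv) > delta
  out <- data.frame(gene = genes[de], delta_vst = dv[de],
                    sign = as.integer(sign(dv[de])),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Select the most variable genes across a cohort
#'
#' Ranks genes by their expression spread across all samples and returns the
#' top `n`. The default criterion is the per-gene range (max - min), with
#' per-gene variance as an alternative; ties are broken by gene id in
#' lexicographic order so the selection is deterministic.
#'
#' @param mat genes x samples numeric matrix with gene rownames.
#' @param n number of genes to return (default 500).
#' @param criterion `"range"` or `"variance"`.
#' @return character vector of gene ids, length `min(n, nrow(mat))`.
#' @export
top_variable_genes <- function(mat, n = 500,
                               criterion = c("range", "variance")) {
  criterion <- match.arg(criterion)
  if (is.null(rownames(mat))) stop("matrix must have gene rownames")
  if (n > nrow(mat)) {
    warning("n exceeds the gene universe; returning all ", nrow(mat),
            " genes")
    n <- nrow(mat)
  }
  stat <- switch(criterion,
    range = apply(mat, 1, function(x) diff(range(x))),
    variance = apply(mat, 1, stats::var))
  ord <- order(-stat, rownames(mat))
  rownames(mat)[ord][seq_len(n)]
}

#' Pairwise cosine distance
#'
#' @param mat samples x features matrix.
#' @return a `dist` object of 1 - cosine similarity.
#' @export
cosine_dist <- function(mat) {
  nrm <- sqrt(rowSums(mat^2))
  zero <- nrm == 0
  if (any(zero))
    stop("zero-norm sample vector(s): ",
         paste(rownames(mat)[zero], collapse = ", "))
  sim <- tcrossprod(mat / nrm)
  sim[sim > 1] <- 1
  sim[sim < -1] <- -1
  stats::as.dist(1 - sim)
}

#' Hierarchical clustering with cosine distance and Ward linkage
#'
#' Clusters samples by 1 - cosine similarity with Ward's minimum-variance
#' linkage (`ward.D2` on the distance matrix). Deterministic for a given
#' input; optionally cuts the dendrogram into `k` groups.
#'
#' @param mat samples x features matrix with sample rownames.
#' @param k number of clusters to cut at, or `NULL` for no labels.
#' @return list: `hclust` (the dendrogram) and `labels` (named integer
#'   vector, `NULL` when `k` is `NULL`).
#' @export
cosine_ward_cluster <- function(mat, k = NULL) {
  if (nrow(mat) < 2) stop("need at least 2 samples to cluster")
  hc <- stats::hclust(cosine_dist(mat), method = "ward.D2")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, labels = labels)
}

#' Nearest-centroid molecular subtype prediction
#'
#' Assigns a sample to the subtype whose centroid profile has the highest
#' Pearson correlation with the sample over the centroid genes. Ties go to
#' the lexicographically first label with a warning. Works for any number of
#' centroid columns (2-, 3- and 4-class schemes alike).
#'
#' @param x named numeric vector, sample expression.
#' @param centroids genes x subtypes matrix with gene rownames and subtype
#'   colnames.
#' @return subtype label (character scalar), with attribute `correlations`.
#' @export
predict_subtype <- function(x, centroids) {
  genes <- intersect(names(x), rownames(centroids))
  if (length(genes) < 3) stop("too few shared genes with the centroids")
  r <- apply(centroids[genes, , drop = FALSE], 2,
             function(ct) stats::cor(x[genes], ct))
  best <- which(r == max(r))
  if (length(best) > 1) {
    warning("centroid correlation tie; taking the lexicographically first")
    best <- best[order(names(r)[best])][1]
  }
  structure(names(r)[best], correlations = r)
}

#' Deconvolve epithelioid/sarcomatoid scores from a sample transcriptome
#'
#' Models the sample as a two-component mixture of an epithelioid-like and a
#' sarcomatoid-like reference profile and estimates the mixing weights by
#' least squares on the simplex: minimize
#' \eqn{\|x - (w_E E + w_S S)\|^2} subject to \eqn{w_E, w_S \ge 0},
#' \eqn{w_E + w_S = 1}. With two components this has the closed form
#' \eqn{w_E = \langle x - S, E - S\rangle / \|E - S\|^2} clipped to
#' \[0, 1\].
#'
#' @param x named numeric vector, sample expression over the marker genes.
#' @param e_profile,s_profile reference profiles over the same genes.
#' @return named numeric vector `c(e_score, s_score)`, summing to 1.
#' @export
deconvolve_es <- function(x, e_profile, s_profile) {
  if (length(e_profile) != length(s_profile) ||
      length(x) != length(e_profile))
    stop("profile and sample lengths differ")
  if (stats::cor(e_profile, s_profile) > 0.999)
    stop("reference profiles are collinear (correlation > 0.999)")
  d <- e_profile - s_profile
  w <- sum((x - s_profile) * d) / sum(d * d)
  w <- min(max(w, 0), 1)
  c(e_score = w, s_score = 1 - w)
}

#' E/S heterogeneity call for a biopsy pair
#'
#' A pair is called heterogeneous at the histo-molecular level when the
#' E score changes by strictly more than `threshold` (default 10 percentage
#' points) between the two biopsies.
#'
#' @param scores_a,scores_b outputs of [deconvolve_es()] for the two sites.
#' @param threshold change threshold, exceeded strictly (default 0.10).
#' @return list: `flag` (logical) and `delta` (absolute E-score change).
#' @export
es_heterogeneity <- function(scores_a, scores_b, threshold = 0.10) {
  delta <- abs(scores_a[["e_score"]] - scores_b[["e_score"]])
  # strict comparison with a guard against floating-point round-off at the
  # threshold itself
  list(flag = delta - threshold > 1e-9, delta = delta)
}
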