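#' Refine marker signatures against tumor cell lines
#'
#' Restricts each cell-population signature to marker genes that are not
#' expressed by tumor cells themselves, so that infiltration scores reflect
#' the microenvironment and not the malignant compartment. A marker is kept
#' when its FPKM is below `expr_threshold` in every cell line. Markers
#' absent from the cell-line matrix cannot be shown expressed and are kept
#' with a warning; named exclusions (e.g. genes missing from an integration
#' dataset) are applied on top. A population losing all of its markers is an
#' error.
#'
#' @param signatures named list of marker-gene vectors per population.
#' @param cell_line_fpkm genes x cell-lines FPKM matrix with gene rownames.
#' @param expr_threshold expression threshold (default 1).
#' @param exclude_genes genes removed by name regardless of expression.
#' @return refined signature list with attribute `removed` (per population).
#' @export
refine_signatures <- function(signatures, cell_line_fpkm,
                              expr_threshold = 1,
                              exclude_genes = character()) {
  removed <- list()
  out <- lapply(names(signatures), function(pop) {
    g <- signatures[[pop]]
    known <- g %in% rownames(cell_line_fpkm)
    if (any(!known))
      warning(sum(!known), " marker(s) of ", pop,
              " absent from the cell-line matrix; treated as not expressed")
    expressed <- rep(FALSE, length(g))
    expressed[known] <- apply(
      cell_line_fpkm[g[known], , drop = FALSE], 1,
      function(x) any(x >= expr_threshold))
    drop <- expressed | g %in% exclude_genes
    removed[[pop]] <<- g[drop]
    g[!drop]
  })
  names(out) <- names(signatures)
  empty <- names(out)[lengths(out) == 0]
  if (length(empty))
    stop("refinement emptied population(s): ", paste(empty, collapse = ", "))
  attr(out, "removed") <- removed
  out
}

#' MCP-counter-style infiltration scores
#'
#' The abundance score of a cell population in a sample is the arithmetic
#' mean of the log2-scale expression of the population's marker genes in
#' that sample. Marker genes missing from the expression matrix are dropped
#' with a warning.
#'
#' @param expr genes x samples matrix of log2-scale expression (VST, or
#'   log2(FPKM + 1)).
#' @param signatures named list of marker-gene vectors.
#' @return populations x samples score matrix.
#' @export
mcp_scores <- function(expr, signatures) {
  if (is.null(rownames(expr))) stop("expression matrix must have rownames")
  scores <- matrix(NA_real_, nrow = length(signatures), ncol = ncol(expr),
                   dimnames = list(names(signatures), colnames(expr)))
  for (pop in names(signatures)) {
    g <- intersect(signatures[[pop]], rownames(expr))
    if (length(g) < length(signatures[[pop]]))
      warning(length(signatures[[pop]]) - length(g), " marker(s) of ", pop,
              " missing from the expression matrix; dropped")
    if (length(g))
      scores[pop, ] <- colMeans(expr[g, , drop = FALSE])
  }
  scores
}

#' Standardize rows within each dataset
#'
#' For cross-cohort integration, centers and scales each row (gene or
#' population) to mean 0 and standard deviation 1 separately within each
#' dataset; the population (denominator n) standard deviation is used, which
#' makes the operation idempotent. Constant rows are set to 0 with a
#' warning.
#'
#' @param mat features x samples matrix.
#' @param datasets character vector of dataset labels, one per column.
#' @return standardized matrix of the same shape.
#' @export
standardize_per_dataset <- function(mat, datasets) {
  if (length(datasets) != ncol(mat))
    stop("one dataset label per column required")
  out <- mat
  warned <- FALSE
  for (ds in unique(datasets)) {
    j <- which(datasets == ds)
    sub <- mat[, j, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- sqrt(rowMeans((sub - mu)^2))
    const <- sdv == 0
    if (any(const) && !warned) {
      warning("constant row(s) within dataset set to 0")
      warned <- TRUE
    }
    sdv[const] <- 1
    z <- (sub - mu) / sdv
    z[const, ] <- 0
    out[, j] <- z
  }
  out
}

#' Assign hot/cold immune status by clustering
#'
#' Clusters samples on their infiltration score profiles (cosine distance,
#' Ward linkage) and cuts at two groups; the cluster with the higher grand
#' mean score is labeled `hot`, the other `cold`. When a pair map is given,
#' patients whose two biopsies fall in different clusters are flagged as
#' mixed — the hot/cold switching phenotype.
#'
#' @param scores populations x samples matrix (typically standardized).
#' @param pairs optional data.frame with `patient`, `sample_a`, `sample_b`.
#' @return list: `labels` (named character vector hot/cold per sample),
#'   `mixed_patients` (character vector, empty without `pairs`), `hclust`.
#' @export
hot_cold_assign <- function(scores, pairs = NULL) {
  smat <- t(scores)
  if (all(apply(smat, 2, function(x) length(unique(x)) == 1)))
    stop("all samples identical: zero-variance clustering input")
  cl <- cosine_ward_cluster(smat, k = 2)
  grand <- tapply(colMeans(scores), cl$labels, mean)
  hot_cluster <- as.integer(names(grand)[which.max(grand)])
  labels <- ifelse(cl$labels == hot_cluster, "hot", "cold")
  names(labels) <- colnames(scores)
  mixed <- character()
  if (!is.null(pairs)) {
    disc <- labels[pairs$sample_a] != labels[pairs$sample_b]
    mixed <- pairs$patient[disc]
  }
  list(labels = labels, mixed_patients = mixed, hclust = cl$hclust)
}

#' Paired Wilcoxon test on population scores
#'
#' Wilcoxon signed-rank test of the vector of population scores between the
#' two biopsies of one patient, using the exact null distribution for up to
#' 25 populations (ties or zero differences fall back to the normal
#' approximation, as usual for the signed-rank test).
#'
#' @param scores_a,scores_b numeric vectors of per-population scores for
#'   sites A and B (same populations, same order).
#' @param exact_max largest n for which the exact distribution is requested
#'   (default 25).
#' @return list: `statistic` (V), `p_value`, `method`.
#' @export
paired_population_test <- function(scores_a, scores_b, exact_max = 25) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors differ in length")
  if (all(scores_a == scores_b))
    return(list(statistic = NA_real_, p_value = 1,
                method = "degenerate (identical vectors)"))
  n <- length(scores_a)
  wt <- suppressWarnings(stats::wilcox.test(
    scores_a, scores_b, paired = TRUE, exact = n <= exact_max))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method)
}

#' Immune-checkpoint differential expression between paired biopsies
#'
#' Per checkpoint gene: when neither biopsy reaches FPKM > 1 the
#' differential expression is set to 0 and the gene is not flagged;
#' otherwise the fold change is the larger FPKM over the smaller one (the
#' denominator floored at `pseudo` to avoid division by zero) and the gene
#' is flagged when the fold change is at least `fc_min`.
#'
#' @param fpkm_a,fpkm_b named numeric vectors of FPKM for the checkpoint
#'   genes in the two biopsies.
#' @param fc_min fold-change flag threshold, met inclusively (default 2).
#' @param pseudo denominator floor (default 0.1).
#' @return data.frame: `gene`, `fpkm_a`, `fpkm_b`, `fold_change` (0 when
#'   both FPKM <= 1), `direction` (`"up_in_A"`, `"up_in_B"` or `"none"`),
#'   `flagged`.
#' @export
checkpoint_de <- function(fpkm_a, fpkm_b, fc_min = 2, pseudo = 0.1) {
  genes <- names(fpkm_a)
  if (is.null(genes) || !identical(genes, names(fpkm_b)))
    stop("inputs must be named by gene, same universe")
  expressed <- pmax(fpkm_a, fpkm_b) > 1
  hi <- pmax(fpkm_a, fpkm_b)
  lo <- pmin(fpkm_a, fpkm_b)
  fc <- ifelse(expressed, hi / pmax(lo, pseudo), 0)
  flagged <- expressed & fc >= fc_min
  direction <- ifelse(!expressed, "none",
                      ifelse(fpkm_a >= fpkm_b, "up_in_A", "up_in_B"))
  data.frame(gene = genes, fpkm_a = fpkm_a, fpkm_b = fpkm_b,
             fold_change = fc, direction = direction, flagged = flagged,
             stringsAsFactors = FALSE, row.names = NULL)
}
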