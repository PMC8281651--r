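#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated, `name<TAB>description`
#' then member genes.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Over-representation analysis of a gene list against gene-set collections
#'
#' For each set, computes the hypergeometric upper-tail probability of
#' drawing at least the observed overlap when sampling `|query|` genes from
#' the universe, adjusts p-values with Benjamini-Hochberg across the
#' collection, and reports the gene ratio (overlap over set size, after
#' intersecting sets with the universe). Sets are significant at
#' FDR < `fdr_max`.
#'
#' @param de_genes character vector, the query gene list (e.g. DE genes);
#'   genes outside the universe are dropped with a warning.
#' @param collection named list of gene sets.
#' @param universe character vector, the background gene universe.
#' @param fdr_max FDR significance cutoff (default 0.05).
#' @return data.frame: `set`, `set_size`, `overlap`, `gene_ratio`, `p`,
#'   `fdr`, `significant`, ordered by raw p.
#' @export
ora <- function(de_genes, collection, universe, fdr_max = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  outside <- setdiff(de_genes, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    de_genes <- intersect(de_genes, universe)
  }
  de_genes <- unique(de_genes)
  N <- length(universe)
  n <- length(de_genes)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    if (K == 0) return(NULL)
    k <- length(intersect(set, de_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k,
               gene_ratio = k / K, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(), set_size = integer(),
                      overlap = integer(), gene_ratio = numeric(),
                      p = numeric(), fdr = numeric(),
                      significant = logical()))
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < fdr_max
  out[order(out$p, out$set), , drop = FALSE]
}

.ssgsea_one <- function(x, set_idx, alpha) {
  n <- length(x)
  ord <- order(x, decreasing = TRUE)
  r <- rank(x, ties.method = "average")  # largest expression = largest rank
  in_set <- logical(n)
  in_set[set_idx] <- TRUE
  in_ord <- in_set[ord]
  w <- abs(r[ord])^alpha
  w[!in_ord] <- 0
  cdf_in <- cumsum(w) / sum(w)
  cdf_out <- cumsum(!in_ord) / sum(!in_ord)
  sum(cdf_in - cdf_out)
}

#' Single-sample GSEA scores
#'
#' Computes per-sample gene-set enrichment scores by the rank-weighted ECDF
#' difference of Barbie et al.: genes are ranked by expression within each
#' sample, and the score is the running sum of the difference between the
#' weighted (rank^alpha) empirical CDF of in-set genes and the unweighted
#' CDF of out-of-set genes. When an FPKM matrix is supplied, genes with
#' FPKM < `fpkm_min` in all samples are removed before ranking. Scores are
#' finally rescaled by the global score range across the whole matrix
#' (when `normalize = TRUE`). Sets with no gene left in the expressed
#' universe yield `NA` scores (undefined, not zero).
#'
#' @param expr genes x samples VST matrix with dimnames.
#' @param collection named list of gene sets.
#' @param alpha rank-weighting exponent (default 0.25).
#' @param fpkm optional genes x samples FPKM matrix for the expression
#'   filter.
#' @param fpkm_min expression filter threshold (default 1).
#' @param normalize divide by the global max - min of the raw scores.
#' @return sets x samples numeric matrix of scores.
#' @export
ssgsea_scores <- function(expr, collection, alpha = 0.25, fpkm = NULL,
                          fpkm_min = 1, normalize = TRUE) {
  if (is.null(rownames(expr))) stop("expression matrix must have rownames")
  if (!is.null(fpkm)) {
    keep <- apply(fpkm, 1, function(x) any(x >= fpkm_min))
    expr <- expr[keep, , drop = FALSE]
  }
  genes <- rownames(expr)
  scores <- matrix(NA_real_, nrow = length(collection), ncol = ncol(expr),
                   dimnames = list(names(collection), colnames(expr)))
  set_idx <- lapply(collection, function(s) which(genes %in% s))
  for (si in seq_along(collection)) {
    idx <- set_idx[[si]]
    if (!length(idx) || length(idx) == length(genes)) next  # undefined
    for (j in seq_len(ncol(expr)))
      scores[si, j] <- .ssgsea_one(expr[, j], idx, alpha)
  }
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  scores
}

#' Paired delta of single-sample GSEA scores
#'
#' The absolute per-set difference of ssGSEA scores between the two biopsies
#' of each patient measures pathway-level intra-tumor heterogeneity; sets
#' are ranked by their delta within each pair.
#'
#' @param scores sets x samples matrix from [ssgsea_scores()].
#' @param pairs data.frame with columns `patient`, `sample_a`, `sample_b`
#'   naming score columns.
#' @return list: `delta` (sets x patients matrix of absolute differences)
#'   and `ranking` (list of set names ordered by decreasing delta per
#'   patient).
#' @export
delta_ssgsea <- function(scores, pairs) {
  missing <- setdiff(c(pairs$sample_a, pairs$sample_b), colnames(scores))
  if (length(missing)) stop("samples absent from score matrix: ",
                            paste(missing, collapse = ", "))
  delta <- sapply(seq_len(nrow(pairs)), function(i)
    abs(scores[, pairs$sample_a[i]] - scores[, pairs$sample_b[i]]))
  delta <- matrix(delta, nrow = nrow(scores),
                  dimnames = list(rownames(scores), pairs$patient))
  ranking <- lapply(seq_len(ncol(delta)), function(j)
    rownames(delta)[order(-delta[, j], rownames(delta))])
  names(ranking) <- pairs$patient
  list(delta = delta, ranking = ranking)
}
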