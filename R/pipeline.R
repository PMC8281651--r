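.default_thresholds <- function() {
  list(ccf_subclonal = 0.5, ci_upper = 1, ccf_max = 1.5,
       de_delta = 1, fpkm_min = 1, dm_delta = 0.2, detp_max = 0.05,
       fdr_max = 0.05, fc_min = 2, es_het = 0.10,
       min_shared_subclone_variants = 2)
}

#' Validate a sample sheet and matrix inputs
#'
#' Distinguishes fatal errors (invalid purity, bad site codes, gene-universe
#' overlap below 90\% between expression layers, dimension disagreement)
#' from warnings (patients without exactly two samples, which paired stages
#' skip).
#'
#' @param sheet sample-sheet data.frame (see [read_sample_sheet()]).
#' @param fpkm,vst,beta,detp optional matrices to cross-check.
#' @param min_overlap minimum shared fraction of gene ids between FPKM and
#'   VST universes (default 0.9).
#' @return list with character vectors `errors` and `warnings`.
#' @export
validate_inputs <- function(sheet, fpkm = NULL, vst = NULL, beta = NULL,
                            detp = NULL, min_overlap = 0.9) {
  errors <- character()
  warnings <- character()
  bad_site <- setdiff(unique(sheet$site), c("A", "B", "C", "D"))
  if (length(bad_site))
    errors <- c(errors, paste("invalid site code(s):",
                              paste(bad_site, collapse = ", ")))
  if (any(sheet$purity <= 0 | sheet$purity > 1))
    errors <- c(errors, "purity outside (0, 1]")
  tab <- table(sheet$patient)
  odd <- names(tab)[tab != 2]
  if (length(odd))
    warnings <- c(warnings,
                  paste("patient(s) without exactly two samples (skipped):",
                        paste(odd, collapse = ", ")))
  if (!is.null(fpkm) && !is.null(vst)) {
    ov <- length(intersect(rownames(fpkm), rownames(vst))) /
      max(length(union(rownames(fpkm), rownames(vst))), 1)
    if (ov < min_overlap)
      errors <- c(errors, sprintf(
        "gene universes of FPKM and VST overlap by %.0f%% (< %.0f%%)",
        100 * ov, 100 * min_overlap))
  }
  if (!is.null(beta) && !is.null(detp) &&
      !identical(dim(beta), dim(detp)))
    errors <- c(errors, "beta and detection-p matrices differ in shape")
  list(errors = errors, warnings = warnings)
}

.resolve <- function(path, base) {
  if (is.null(path)) return(NULL)
  if (file.exists(path)) path else file.path(base, path)
}

.read_config <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(normalizePath(config_path))
  for (key in c("sample_sheet", "fpkm", "vst", "beta", "detp",
                "cpg_annotation", "es_profiles", "centroids",
                "es_correlated_genes", "signatures", "gene_sets",
                "checkpoint_genes"))
    cfg[[key]] <- .resolve(cfg[[key]], base)
  if (is.null(cfg$outdir)) cfg$outdir <- file.path(base, "results")
  else if (!grepl("^/", cfg$outdir)) cfg$outdir <- file.path(base, cfg$outdir)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  thr <- .default_thresholds()
  for (nm in names(cfg$thresholds)) thr[[nm]] <- cfg$thresholds[[nm]]
  cfg$thresholds <- thr
  cfg
}

.clonality_stage <- function(pair_sheet, cfg, pdir) {
  thr <- cfg$thresholds
  va <- read_variants(pair_sheet$variants[1])
  vb <- read_variants(pair_sheet$variants[2])
  has_seg <- "segments" %in% names(pair_sheet) &&
    !any(is.na(pair_sheet$segments))
  sa <- if (has_seg) read_segments(pair_sheet$segments[1]) else NULL
  sb <- if (has_seg) read_segments(pair_sheet$segments[2]) else NULL
  calls <- pair_clonality(va, vb, pair_sheet$purity[1], pair_sheet$purity[2],
                          segments_a = sa, segments_b = sb,
                          ccf_max = thr$ccf_max,
                          ccf_threshold = thr$ccf_subclonal,
                          ci_upper = thr$ci_upper)
  .write_tsv(calls, file.path(pdir, "clonality_calls.tsv"))
  cnv <- NULL
  if (has_seg) {
    cnv <- match_and_classify_cnv(sa, sb, pair_sheet$purity[1],
                                  pair_sheet$purity[2],
                                  ccf_threshold = thr$ccf_subclonal)
    .write_tsv(cnv$calls, file.path(pdir, "cnv_calls.tsv"))
  }
  shared_sub <- detect_shared_subclone(
    calls, cnv_calls = cnv$calls,
    min_variants = thr$min_shared_subclone_variants)
  tree <- build_clonal_tree(calls)
  jsonlite::write_json(lapply(unclass(tree), function(nd)
    nd[c("id", "parent", "sites", "n_variants")]),
    file.path(pdir, "clonal_tree.json"), auto_unbox = TRUE, pretty = TRUE)
  cat_counts <- table(factor(calls$category,
                             levels = .clonality_categories))
  list(category_counts = as.list(cat_counts),
       shared_subclone = shared_sub[c("flag", "n_support",
                                      "supporting_variants",
                                      "cancer_genes", "cnv_corroborated")],
       n_cnv_calls = if (is.null(cnv)) NULL else nrow(cnv$calls))
}

.expression_stage <- function(pair_sheet, cfg, pdir, fpkm, vst) {
  thr <- cfg$thresholds
  sa <- pair_sheet$sample[1]
  sb <- pair_sheet$sample[2]
  de <- call_de_genes(fpkm[, sa], fpkm[, sb], vst[, sa], vst[, sb],
                      delta = thr$de_delta, fpkm_min = thr$fpkm_min)
  .write_tsv(de, file.path(pdir, "de_genes.tsv"))
  out <- list(n_de = nrow(de), de_genes = de$gene, de_sign = de$sign)
  if (!is.null(cfg$es_profiles)) {
    prof <- utils::read.delim(cfg$es_profiles, stringsAsFactors = FALSE)
    g <- intersect(prof$gene, rownames(vst))
    pe <- prof$E[match(g, prof$gene)]
    ps <- prof$S[match(g, prof$gene)]
    es_a <- deconvolve_es(vst[g, sa], pe, ps)
    es_b <- deconvolve_es(vst[g, sb], pe, ps)
    het <- es_heterogeneity(es_a, es_b, threshold = thr$es_het)
    out$es_scores <- list(A = as.list(es_a), B = as.list(es_b))
    out$es_heterogeneous <- het$flag
    out$es_delta <- het$delta
    out$es_delta_signed <- es_a[["e_score"]] - es_b[["e_score"]]
  }
  if (!is.null(cfg$centroids)) {
    cent <- utils::read.delim(cfg$centroids, stringsAsFactors = FALSE)
    cmat <- as.matrix(cent[, -1, drop = FALSE])
    rownames(cmat) <- cent[[1]]
    out$subtype <- list(A = as.character(predict_subtype(vst[, sa], cmat)),
                        B = as.character(predict_subtype(vst[, sb], cmat)))
  }
  out
}

.methylation_stage <- function(pair_sheet, cfg, pdir, beta, detp,
                               expr_out) {
  thr <- cfg$thresholds
  sa <- pair_sheet$sample[1]
  sb <- pair_sheet$sample[2]
  dm <- call_dm_cpg(beta[, sa], beta[, sb], detp[, sa], detp[, sb],
                    delta = thr$dm_delta, p_max = thr$detp_max)
  .write_tsv(dm, file.path(pdir, "dm_cpgs.tsv"))
  out <- list(n_dm = nrow(dm))
  if (!is.null(cfg$cpg_annotation) && !is.null(expr_out$de_genes)) {
    ann <- utils::read.delim(cfg$cpg_annotation, stringsAsFactors = FALSE)
    dd <- de_dm_genes(expr_out$de_genes, dm$cpg, ann)
    out$n_de_dm <- length(dd$genes)
    out$de_dm_percentage <- dd$percentage
    out$de_dm_genes <- dd$genes
    if (!is.null(cfg$es_correlated_genes) &&
        !is.null(expr_out$es_delta_signed)) {
      es_tab <- utils::read.delim(cfg$es_correlated_genes,
                                  stringsAsFactors = FALSE)
      dedm_signed <- data.frame(
        gene = dd$genes,
        sign = expr_out$de_sign[match(dd$genes, expr_out$de_genes)])
      cons <- withCallingHandlers(
        direction_consistency_filter(dedm_signed, es_tab,
                                     expr_out$es_delta_signed),
        warning = function(w) invokeRestart("muffleWarning"))
      out$direction_consistent <- cons$kept
      out$direction_consistent_proportion <- cons$proportion
    }
  }
  out
}

.pathway_stage <- function(pair_sheet, cfg, pdir, expr_out, universe,
                           ssgsea, pairs) {
  thr <- cfg$thresholds
  sets <- read_gmt(cfg$gene_sets)
  out <- list()
  if (!is.null(expr_out$de_genes)) {
    res <- ora(expr_out$de_genes, sets, universe, fdr_max = thr$fdr_max)
    .write_tsv(res, file.path(pdir, "ora.tsv"))
    out$ora_significant <- res$set[res$significant]
    out$ora_gene_ratio <- stats::setNames(
      as.list(res$gene_ratio[res$significant]), res$set[res$significant])
  }
  if (!is.null(ssgsea)) {
    p <- pairs[pairs$patient == pair_sheet$patient[1], , drop = FALSE]
    d <- delta_ssgsea(ssgsea, p)
    out$top_delta_ssgsea <- utils::head(d$ranking[[1]], 5)
    out$delta_ssgsea <- as.list(stats::setNames(d$delta[, 1],
                                                rownames(d$delta)))
  }
  out
}

#' Run the multi-omics heterogeneity pipeline from a config file
#'
#' Orchestrates per-patient paired analyses over whichever omic layers the
#' config provides: clonality (variants, optional segments), expression
#' (DE calling, E/S deconvolution, subtype prediction), methylation
#' (DM calling, DE_DM intersection, direction-consistency filter), pathway
#' scoring (ORA, ssGSEA deltas) and microenvironment profiling (MCP scores,
#' per-dataset standardization, hot/cold clustering, paired Wilcoxon,
#' checkpoint fold changes). Patients without exactly two samples are
#' skipped with a log line. Identical config and inputs produce identical
#' outputs.
#'
#' The YAML config holds file paths (`sample_sheet` required; `fpkm`,
#' `vst`, `beta`, `detp`, `cpg_annotation`, `es_profiles`, `centroids`,
#' `es_correlated_genes`, `signatures`, `gene_sets`, `checkpoint_genes`
#' optional), `outdir`, `seed` and an optional `thresholds` block
#' overriding the defaults (CCF 0.5, CI upper 1, VST delta 1, beta delta
#' 0.2, FDR 0.05, fold change 2, E/S 10\%).
#'
#' @param config_path path to the YAML config.
#' @return named list of per-patient heterogeneity reports (also written as
#'   `report.json` under each patient's output directory), invisibly.
#' @export
run_pipeline <- function(config_path) {
  cfg <- .read_config(config_path)
  thr <- cfg$thresholds
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("mesohet ", as.character(utils::packageVersion("mesohet"))),
    paste0("seed: ", cfg$seed),
    paste0("thresholds: ",
           paste(names(thr), unlist(thr), sep = "=", collapse = " ")))
  set.seed(cfg$seed)

  sheet <- read_sample_sheet(cfg$sample_sheet)
  base <- dirname(normalizePath(cfg$sample_sheet))
  for (col in c("variants", "segments")) if (col %in% names(sheet))
    sheet[[col]] <- vapply(sheet[[col]], .resolve, character(1), base = base)

  fpkm <- if (!is.null(cfg$fpkm)) read_matrix_tsv(cfg$fpkm)
  vst <- if (!is.null(cfg$vst)) read_matrix_tsv(cfg$vst)
  beta <- if (!is.null(cfg$beta)) read_matrix_tsv(cfg$beta)
  detp <- if (!is.null(cfg$detp)) read_matrix_tsv(cfg$detp)
  val <- validate_inputs(sheet, fpkm, vst, beta, detp)
  if (length(val$errors))
    stop("input validation failed:\n  ",
         paste(val$errors, collapse = "\n  "))
  log_lines <- c(log_lines, val$warnings)

  tab <- table(sheet$patient)
  patients <- sort(names(tab)[tab == 2])
  for (p in sort(names(tab)[tab != 2]))
    log_lines <- c(log_lines,
                   paste0("skipping patient ", p, ": ", tab[p],
                          " sample(s), paired design requires 2"))
  pairs <- do.call(rbind, lapply(patients, function(p) {
    ps <- sheet[sheet$patient == p, , drop = FALSE]
    ps <- ps[order(ps$site, ps$sample), , drop = FALSE]
    data.frame(patient = p, sample_a = ps$sample[1], sample_b = ps$sample[2],
               stringsAsFactors = FALSE)
  }))

  # cohort-level computations shared across patients
  ssgsea <- NULL
  universe <- NULL
  if (!is.null(vst)) universe <- rownames(vst)
  if (!is.null(vst) && !is.null(cfg$gene_sets)) {
    sets <- read_gmt(cfg$gene_sets)
    ssgsea <- ssgsea_scores(vst, sets, fpkm = fpkm,
                            fpkm_min = thr$fpkm_min)
    write_matrix_tsv(ssgsea, file.path(cfg$outdir, "ssgsea_scores.tsv"),
                     id_col = "set")
  }
  micro <- NULL
  if (!is.null(vst) && !is.null(cfg$signatures)) {
    sig_df <- utils::read.delim(cfg$signatures, stringsAsFactors = FALSE)
    signatures <- split(sig_df$gene, sig_df$population)
    scores <- mcp_scores(vst, signatures)
    z <- standardize_per_dataset(
      scores, if ("dataset" %in% names(sheet))
        sheet$dataset[match(colnames(scores), sheet$sample)]
      else rep("all", ncol(scores)))
    hc <- hot_cold_assign(z, pairs)
    write_matrix_tsv(scores, file.path(cfg$outdir, "mcp_scores.tsv"),
                     id_col = "population")
    .write_tsv(data.frame(sample = names(hc$labels), label = hc$labels,
                          row.names = NULL),
               file.path(cfg$outdir, "hot_cold.tsv"))
    micro <- list(scores = scores, z = z, hc = hc)
  }
  checkpoints <- if (!is.null(cfg$checkpoint_genes))
    readLines(cfg$checkpoint_genes)

  reports <- list()
  for (p in patients) {
    ps <- sheet[sheet$patient == p, , drop = FALSE]
    ps <- ps[order(ps$site, ps$sample), , drop = FALSE]
    pdir <- file.path(cfg$outdir, p)
    dir.create(pdir, showWarnings = FALSE)
    report <- list(schema_version = "1.0", patient = p,
                   samples = as.list(stats::setNames(ps$sample, ps$site)),
                   purity = as.list(stats::setNames(ps$purity, ps$site)))
    if ("variants" %in% names(ps) && all(!is.na(ps$variants)))
      report$clonality <- .clonality_stage(ps, cfg, pdir)
    expr_out <- NULL
    if (!is.null(fpkm) && !is.null(vst)) {
      expr_out <- .expression_stage(ps, cfg, pdir, fpkm, vst)
      report$expression <- expr_out[setdiff(names(expr_out),
                                            c("de_genes", "de_sign"))]
    }
    if (!is.null(beta) && !is.null(detp))
      report$methylation <- .methylation_stage(ps, cfg, pdir, beta, detp,
                                               expr_out)
    if (!is.null(cfg$gene_sets) && !is.null(vst))
      report$pathways <- .pathway_stage(ps, cfg, pdir, expr_out, universe,
                                        ssgsea, pairs)
    if (!is.null(micro)) {
      sa <- ps$sample[1]
      sb <- ps$sample[2]
      wt <- paired_population_test(micro$z[, sa], micro$z[, sb])
      report$microenvironment <- list(
        hot_cold = list(A = unname(micro$hc$labels[sa]),
                        B = unname(micro$hc$labels[sb])),
        mixed_pair = p %in% micro$hc$mixed_patients,
        wilcoxon_p = wt$p_value)
      if (!is.null(checkpoints) && !is.null(fpkm)) {
        ck <- intersect(checkpoints, rownames(fpkm))
        cd <- checkpoint_de(fpkm[ck, sa], fpkm[ck, sb],
                            fc_min = thr$fc_min)
        .write_tsv(cd, file.path(pdir, "checkpoint_de.tsv"))
        report$microenvironment$checkpoint_flagged <- cd$gene[cd$flagged]
      }
    }
    jsonlite::write_json(report, file.path(pdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    reports[[p]] <- report
  }
  writeLines(log_lines, file.path(cfg$outdir, "run_log.txt"))
  invisible(reports)
}
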