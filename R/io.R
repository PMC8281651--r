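#' Read a somatic variant table (TSV dialect or VCF)
#'
#' The TSV dialect has one row per variant with columns `chrom`, `pos`,
#' `ref`, `alt`, `alt_count`, `depth` and optionally `gene`, `consequence`,
#' `sift`, `polyphen`, `cancer_gene`, `sample_id`. Files ending in `.vcf`
#' are parsed with the vcfR package, taking the alt count from the `AD`
#' FORMAT field and depth from `DP` (first sample column).
#'
#' @param path path to a `.tsv` or `.vcf` file.
#' @return variant observation data.frame.
#' @export
read_variants <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ad <- vcfR::extract.gt(v, element = "AD")[, 1]
    dp <- as.integer(vcfR::extract.gt(v, element = "DP")[, 1])
    alt_count <- vapply(strsplit(ad, ",", fixed = TRUE),
                        function(x) as.integer(x[2]), integer(1))
    fix <- vcfR::getFIX(v)
    out <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      alt_count = alt_count, depth = dp,
                      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "alt_count", "depth")
    miss <- setdiff(need, names(out))
    if (length(miss))
      stop("variant table ", path, " lacks column(s): ",
           paste(miss, collapse = ", "))
  }
  bad <- which(out$depth <= 0 | out$alt_count < 0 |
                 out$alt_count > out$depth)
  if (length(bad))
    stop("malformed variant record(s) in ", path, " at line(s): ",
         paste(utils::head(bad, 5) + 1, collapse = ", "))
  out
}

#' Read an allele-specific copy-number segment table
#'
#' SEG-like TSV with columns `chrom`, `start`, `end`, `total_cn`,
#' `major_cn`, `minor_cn` and optionally `cellular_fraction`, `sample_id`.
#'
#' @param path path to a TSV file.
#' @return segment data.frame.
#' @export
read_segments <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "total_cn", "major_cn", "minor_cn")
  miss <- setdiff(need, names(seg))
  if (length(miss))
    stop("segment table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (any(seg$start > seg$end)) stop("segment with start > end in ", path)
  if (any(seg$major_cn < seg$minor_cn))
    stop("major_cn < minor_cn in ", path)
  if (any(seg$major_cn + seg$minor_cn != seg$total_cn))
    stop("major_cn + minor_cn != total_cn in ", path)
  seg
}

#' Read a feature-by-sample matrix from TSV
#'
#' The first column holds feature ids (genes, CpGs); remaining columns are
#' samples.
#'
#' @param path path to a TSV file.
#' @return numeric matrix with feature rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Write a feature-by-sample matrix to TSV
#'
#' @param mat matrix with rownames.
#' @param path output path.
#' @param id_col name for the feature-id column (default `"feature"`).
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sample sheet
#'
#' Columns: `patient`, `sample`, `site` (A/B/C/D), `purity`, `dataset`, and
#' optional per-layer file-path columns (`variants`, `segments`).
#'
#' @param path path to a TSV file.
#' @return sample-sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient", "sample", "site", "purity")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  sheet
}

#' Select the biopsy pair with the closest tumor purity
#'
#' When a patient has more than two samples, paired analyses use the two
#' samples minimizing the absolute purity difference (ties broken by sample
#' id order).
#'
#' @param sheet sample-sheet rows of one patient.
#' @return two-row subset of `sheet`.
#' @export
select_closest_purity_pair <- function(sheet) {
  if (nrow(sheet) < 2) stop("need at least two samples")
  if (nrow(sheet) == 2) return(sheet)
  cmb <- utils::combn(nrow(sheet), 2)
  d <- abs(sheet$purity[cmb[1, ]] - sheet$purity[cmb[2, ]])
  best <- cmb[, which.min(d)]
  sheet[sort(best), , drop = FALSE]
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Materializes a [simulate_cohort()] object as the TSV files the pipeline
#' reads: per-sample variant and segment tables, cohort-wide FPKM/VST and
#' methylation matrices, the CpG annotation, E/S reference profiles (also
#' used as 2-class centroids), immune signature table, a GMT gene-set
#' collection built from the simulation's marker sets, the E/S-correlated
#' gene table, a checkpoint gene list, a sample sheet, a ready-to-run
#' pipeline config, and the ground-truth JSON for test harnesses.
#'
#' @param cohort a `"synthetic_cohort"` object.
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the config for the pipeline run.
#' @return the config file path, invisibly.
#' @export
write_cohort <- function(cohort, dir, seed = 1) {
  dir.create(file.path(dir, "variants"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "segments"), showWarnings = FALSE)
  pats <- names(cohort$patients)
  sheet <- list()
  for (p in pats) {
    pe <- cohort$patients[[p]]
    for (s in c("A", "B")) {
      sid <- paste0(p, "_", s)
      v <- pe$reads[[s]]
      v$sample_id <- sid
      .write_tsv(v, file.path(dir, "variants", paste0(sid, ".tsv")))
      purity <- pe$clone_sim$compositions[[s]]$purity
      seg <- data.frame(
        sample_id = sid,
        chrom = c("chr1", "chr2"),
        start = c(1L, 1L), end = c(50000000L, 80000000L),
        total_cn = c(3L, 1L), major_cn = c(2L, 1L), minor_cn = c(1L, 0L),
        cellular_fraction = c(purity, purity))
      .write_tsv(seg, file.path(dir, "segments", paste0(sid, ".tsv")))
      sheet[[sid]] <- data.frame(
        patient = p, sample = sid, site = s, purity = purity,
        dataset = "synthetic",
        variants = file.path("variants", paste0(sid, ".tsv")),
        segments = file.path("segments", paste0(sid, ".tsv")),
        stringsAsFactors = FALSE)
    }
  }
  sheet <- do.call(rbind, sheet)
  .write_tsv(sheet, file.path(dir, "sample_sheet.tsv"))

  samples <- sheet$sample
  fpkm <- sapply(pats, function(p) cohort$patients[[p]]$expression$fpkm)
  fpkm <- matrix(unlist(lapply(pats, function(p)
    cohort$patients[[p]]$expression$fpkm)), nrow = length(cohort$genes),
    dimnames = list(cohort$genes, samples))
  vst <- matrix(unlist(lapply(pats, function(p)
    cohort$patients[[p]]$expression$vst)), nrow = length(cohort$genes),
    dimnames = list(cohort$genes, samples))
  write_matrix_tsv(fpkm, file.path(dir, "fpkm.tsv"), id_col = "gene")
  write_matrix_tsv(vst, file.path(dir, "vst.tsv"), id_col = "gene")

  n_cpg <- nrow(cohort$patients[[1]]$methylation$beta)
  cpg <- cohort$patients[[1]]$methylation$cpg
  beta <- matrix(unlist(lapply(pats, function(p)
    cohort$patients[[p]]$methylation$beta)), nrow = n_cpg,
    dimnames = list(cpg, samples))
  detp <- matrix(unlist(lapply(pats, function(p)
    cohort$patients[[p]]$methylation$detp)), nrow = n_cpg,
    dimnames = list(cpg, samples))
  write_matrix_tsv(beta, file.path(dir, "beta.tsv"), id_col = "cpg")
  write_matrix_tsv(detp, file.path(dir, "detp.tsv"), id_col = "cpg")
  .write_tsv(cohort$patients[[1]]$methylation$annotation,
             file.path(dir, "cpg_annotation.tsv"))

  prof <- cohort$es_profiles
  .write_tsv(data.frame(gene = rownames(prof), E = prof[, "E"],
                        S = prof[, "S"]),
             file.path(dir, "es_profiles.tsv"))
  sig_df <- do.call(rbind, lapply(names(cohort$immune_signatures), function(p)
    data.frame(population = p, gene = cohort$immune_signatures[[p]],
               stringsAsFactors = FALSE)))
  .write_tsv(sig_df, file.path(dir, "signatures.tsv"))

  e_mark <- attr(prof, "e_markers")
  s_mark <- attr(prof, "s_markers")
  set.seed(seed)
  sets <- c(list(epithelioid_markers = e_mark, sarcomatoid_markers = s_mark),
            cohort$immune_signatures,
            list(random_set_1 = sample(cohort$genes, 40),
                 random_set_2 = sample(cohort$genes, 60)))
  write_gmt(sets, file.path(dir, "gene_sets.gmt"))
  .write_tsv(data.frame(
    gene = c(e_mark, s_mark),
    sign = rep(c("positive_with_E", "positive_with_S"),
               c(length(e_mark), length(s_mark)))),
    file.path(dir, "es_correlated_genes.tsv"))
  checkpoints <- unlist(lapply(cohort$immune_signatures[1:4],
                               utils::head, 2), use.names = FALSE)
  writeLines(checkpoints, file.path(dir, "checkpoint_genes.txt"))

  truth <- list(
    scenarios = as.list(cohort$truth$scenarios),
    hot_status = cohort$truth$hot_status,
    mixed_pair_patient = cohort$truth$mixed_pair_patient,
    categories = lapply(cohort$patients, function(pe)
      as.list(pe$clone_sim$truth$category)),
    de_genes = lapply(cohort$patients, function(pe)
      pe$expression$de_truth$gene),
    dm_cpgs = lapply(cohort$patients, function(pe)
      pe$methylation$dm_truth$cpg),
    es_scores = lapply(cohort$patients, function(pe)
      as.list(as.data.frame(pe$expression$es_scores))))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  config <- list(
    sample_sheet = "sample_sheet.tsv",
    fpkm = "fpkm.tsv", vst = "vst.tsv",
    beta = "beta.tsv", detp = "detp.tsv",
    cpg_annotation = "cpg_annotation.tsv",
    es_profiles = "es_profiles.tsv",
    centroids = "es_profiles.tsv",
    es_correlated_genes = "es_correlated_genes.tsv",
    signatures = "signatures.tsv",
    gene_sets = "gene_sets.gmt",
    checkpoint_genes = "checkpoint_genes.txt",
    outdir = "results",
    seed = seed)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}
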