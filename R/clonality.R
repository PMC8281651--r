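#' Is a missense variant predicted damaging?
#'
#' A variant counts as damaging when at least one of SIFT or PolyPhen predicts
#' a deleterious effect. Unknown or missing predictions never count as
#' damaging.
#'
#' @param sift_label character vector of SIFT predictions; one of
#'   `"deleterious"`, `"tolerated"`, `"unknown"` (NA treated as unknown).
#' @param polyphen_label character vector of PolyPhen predictions; one of
#'   `"probably_damaging"`, `"possibly_damaging"`, `"benign"`, `"unknown"`
#'   (NA treated as unknown).
#' @return logical vector, `TRUE` where at least one tool predicts damage.
#' @examples
#' is_damaging("tolerated", "probably_damaging")  # TRUE
#' is_damaging("deleterious", "unknown")          # TRUE
#' is_damaging("tolerated", "benign")             # FALSE
#' @export
is_damaging <- function(sift_label, polyphen_label) {
  sift_ok <- c("deleterious", "tolerated", "unknown")
  poly_ok <- c("probably_damaging", "possibly_damaging", "benign", "unknown")
  sift_label <- ifelse(is.na(sift_label), "unknown", as.character(sift_label))
  polyphen_label <- ifelse(is.na(polyphen_label), "unknown",
                           as.character(polyphen_label))
  bad_s <- setdiff(unique(sift_label), sift_ok)
  if (length(bad_s))
    stop("unrecognized SIFT label(s): ", paste(bad_s, collapse = ", "),
         "; accepted: ", paste(sift_ok, collapse = ", "))
  bad_p <- setdiff(unique(polyphen_label), poly_ok)
  if (length(bad_p))
    stop("unrecognized PolyPhen label(s): ", paste(bad_p, collapse = ", "),
         "; accepted: ", paste(poly_ok, collapse = ", "))
  sift_label == "deleterious" |
    polyphen_label %in% c("probably_damaging", "possibly_damaging")
}

#' Estimate the cancer cell fraction of a variant
#'
#' Converts a variant allele frequency into the fraction of tumor cells
#' carrying the variant, correcting for tumor purity, local total copy number
#' and mutation multiplicity. With purity \eqn{p}, tumor total copy number
#' \eqn{C_t} and normal copy number \eqn{C_n},
#' \deqn{raw = VAF (p C_t + (1-p) C_n) / p,}
#' multiplicity is the nearest integer to \eqn{raw} clamped to
#' \eqn{[1, major\_cn]} (1 when no segment is supplied), and
#' \eqn{CCF = raw / multiplicity}. The 95\% interval applies the same
#' transform to an exact Clopper-Pearson binomial interval on the VAF.
#' Estimates above `ccf_max` are capped and flagged, never silently
#' renormalized.
#'
#' @param alt_count,depth integer vectors of alt-supporting reads and total
#'   depth; `depth > 0`, `0 <= alt_count <= depth`.
#' @param purity tumor purity in (0, 1].
#' @param total_cn,major_cn tumor total and major-allele copy number at the
#'   locus; `major_cn = NULL` means no segment available (multiplicity fixed
#'   at 1 and `total_cn` defaults to 2).
#' @param normal_cn copy number in contaminating normal cells (default 2).
#' @param ccf_max cap applied to the reported CCF and interval bounds
#'   (default 1.5).
#' @param conf_level confidence level for the binomial interval.
#' @return data.frame with columns `vaf`, `ccf`, `ci_low`, `ci_high`,
#'   `multiplicity`, `purity`, `total_cn`, `capped`, and `ccf_raw` (the
#'   uncapped multiplicity-corrected value).
#' @examples
#' estimate_ccf(50, 100, purity = 1)            # clonal heterozygous, CCF 1
#' estimate_ccf(30, 100, purity = 0.6)          # CCF 1 after purity correction
#' @export
estimate_ccf <- function(alt_count, depth, purity, total_cn = 2,
                         major_cn = NULL, normal_cn = 2, ccf_max = 1.5,
                         conf_level = 0.95) {
  n <- max(length(alt_count), length(depth), length(total_cn))
  alt_count <- rep_len(alt_count, n)
  depth <- rep_len(depth, n)
  total_cn <- rep_len(total_cn, n)
  if (any(purity <= 0) || any(purity > 1))
    stop("purity must be in (0, 1]")
  if (any(depth <= 0)) stop("depth must be positive")
  if (any(alt_count < 0 | alt_count > depth))
    stop("alt_count must be in [0, depth]")
  if (any(total_cn == 0))
    stop("total_cn = 0: a variant cannot reside on zero copies")
  has_seg <- !is.null(major_cn)
  mmax <- if (has_seg) rep_len(major_cn, n) else rep(1L, n)
  if (has_seg && any(mmax < 1))
    stop("major_cn must be >= 1 where a segment is supplied")

  vaf <- alt_count / depth
  denom <- purity * total_cn + (1 - purity) * normal_cn
  raw <- vaf * denom / purity
  mult <- pmin(pmax(round(raw), 1), mmax)
  ccf_raw <- raw / mult

  alpha <- 1 - conf_level
  lo_v <- ifelse(alt_count == 0, 0,
                 stats::qbeta(alpha / 2, alt_count, depth - alt_count + 1))
  hi_v <- ifelse(alt_count == depth, 1,
                 stats::qbeta(1 - alpha / 2, alt_count + 1, depth - alt_count))
  ci_low_raw <- lo_v * denom / purity / mult
  ci_high_raw <- hi_v * denom / purity / mult

  capped <- ccf_raw > ccf_max
  data.frame(
    vaf = vaf,
    ccf = pmin(ccf_raw, ccf_max),
    ci_low = pmin(ci_low_raw, ccf_max),
    ci_high = pmin(ci_high_raw, ccf_max),
    multiplicity = as.integer(mult),
    purity = rep_len(purity, n),
    total_cn = total_cn,
    capped = capped,
    ccf_raw = ccf_raw
  )
}

#' CCF of a copy-number alteration
#'
#' The CCF of a copy-number event is its cellular fraction (fraction of all
#' cells carrying the event, as emitted by allele-specific copy-number
#' callers) divided by tumor purity. Quotients above 1 + `tol` trigger a
#' warning (usually a purity misestimate); the returned value is capped at 1.
#'
#' @param cellular_fraction fraction of all sampled cells bearing the event,
#'   in \[0, 1\].
#' @param purity tumor purity in (0, 1].
#' @param tol tolerance above 1 before the over-unity warning fires.
#' @return numeric vector of CNV CCFs in \[0, 1\].
#' @export
cnv_ccf <- function(cellular_fraction, purity, tol = 0.1) {
  if (any(purity <= 0)) stop("purity must be > 0")
  if (any(cellular_fraction < 0 | cellular_fraction > 1))
    stop("cellular_fraction must be in [0, 1]")
  q <- cellular_fraction / purity
  if (any(q > 1 + tol))
    warning("CNV CCF exceeds 1 + ", tol,
            " before capping; purity may be misestimated")
  pmin(q, 1)
}

.clonality_categories <- c("clonal_shared", "subclonal_shared",
                           "clonal_private", "subclonal_private")

#' Classify one variant across a biopsy pair
#'
#' A variant is *shared* when observed in both paired biopsies, *private*
#' otherwise. A shared variant is *subclonal* only when the CCF is below 0.5
#' in both samples and the upper 95\% bound is below 1 in both samples; a
#' private variant is subclonal when its single CCF is below 0.5 and its
#' upper bound below 1. Everything else is clonal.
#'
#' @param est_a,est_b one-row data.frames from [estimate_ccf()], or `NULL`
#'   when the variant was not observed at that site.
#' @param ccf_threshold subclonality CCF cutoff (default 0.5).
#' @param ci_upper upper-bound cutoff for the confidence-interval rule
#'   (default 1).
#' @return one of `"clonal_shared"`, `"subclonal_shared"`,
#'   `"clonal_private"`, `"subclonal_private"`.
#' @export
classify_variant <- function(est_a = NULL, est_b = NULL,
                             ccf_threshold = 0.5, ci_upper = 1) {
  if (is.null(est_a) && is.null(est_b))
    stop("variant absent from both samples: nothing to classify")
  shared <- !is.null(est_a) && !is.null(est_b)
  sub_ok <- function(e)
    e$ccf < ccf_threshold && e$ci_high < ci_upper
  if (shared) {
    if (sub_ok(est_a) && sub_ok(est_b)) "subclonal_shared" else "clonal_shared"
  } else {
    e <- if (is.null(est_a)) est_b else est_a
    if (sub_ok(e)) "subclonal_private" else "clonal_private"
  }
}

.variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

.find_segment <- function(segments, chrom, pos) {
  if (is.null(segments)) return(NULL)
  hit <- which(segments$chrom == chrom & segments$start <= pos &
                 segments$end >= pos)
  if (!length(hit)) NULL else segments[hit[1L], , drop = FALSE]
}

#' Classify all variants of a biopsy pair
#'
#' Matches variant observations across a biopsy pair by
#' chrom:pos:ref:alt, estimates per-site CCFs (using the local copy-number
#' segment when supplied) and assigns the four-way clonality category.
#'
#' @param vars_a,vars_b variant tables for the two sites (see
#'   [read_variants()] for the columns; `alt_count`, `depth`, `chrom`,
#'   `pos`, `ref`, `alt` required, `gene`/`cancer_gene` optional).
#' @param purity_a,purity_b tumor purities of the two biopsies.
#' @param segments_a,segments_b optional copy-number segment tables
#'   (columns `chrom`, `start`, `end`, `total_cn`, `major_cn`, `minor_cn`).
#' @param ... passed to [estimate_ccf()] / [classify_variant()]
#'   (`ccf_max`, `ccf_threshold`, `ci_upper`).
#' @return data.frame of clonality calls: variant key, gene, per-site CCF
#'   estimates (NA when absent) and `category`.
#' @export
pair_clonality <- function(vars_a, vars_b, purity_a, purity_b,
                           segments_a = NULL, segments_b = NULL, ...) {
  dots <- list(...)
  est_args <- dots[names(dots) %in% c("ccf_max", "normal_cn", "conf_level")]
  cls_args <- dots[names(dots) %in% c("ccf_threshold", "ci_upper")]
  key_a <- if (nrow(vars_a)) .variant_key(vars_a) else character()
  key_b <- if (nrow(vars_b)) .variant_key(vars_b) else character()
  if (anyDuplicated(key_a) || anyDuplicated(key_b))
    stop("duplicated variant keys within one sample")
  keys <- union(key_a, key_b)

  one_site <- function(vars, keys_site, purity, segments, key) {
    i <- match(key, keys_site)
    if (is.na(i)) return(NULL)
    v <- vars[i, , drop = FALSE]
    seg <- .find_segment(segments, v$chrom, v$pos)
    args <- c(list(alt_count = v$alt_count, depth = v$depth, purity = purity,
                   total_cn = if (is.null(seg)) 2 else seg$total_cn,
                   major_cn = if (is.null(seg)) NULL else seg$major_cn),
              est_args)
    do.call(estimate_ccf, args)
  }

  rows <- lapply(keys, function(k) {
    ea <- one_site(vars_a, key_a, purity_a, segments_a, k)
    eb <- one_site(vars_b, key_b, purity_b, segments_b, k)
    cat <- do.call(classify_variant, c(list(est_a = ea, est_b = eb), cls_args))
    src <- if (!is.null(ea)) vars_a[match(k, key_a), , drop = FALSE]
           else vars_b[match(k, key_b), , drop = FALSE]
    data.frame(
      key = k,
      gene = if ("gene" %in% names(src)) src$gene else NA_character_,
      cancer_gene = if ("cancer_gene" %in% names(src))
        isTRUE(src$cancer_gene) else FALSE,
      ccf_a = if (is.null(ea)) NA_real_ else ea$ccf,
      ci_low_a = if (is.null(ea)) NA_real_ else ea$ci_low,
      ci_high_a = if (is.null(ea)) NA_real_ else ea$ci_high,
      ccf_b = if (is.null(eb)) NA_real_ else eb$ccf,
      ci_low_b = if (is.null(eb)) NA_real_ else eb$ci_low,
      ci_high_b = if (is.null(eb)) NA_real_ else eb$ci_high,
      category = cat,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(key = character(), gene = character(),
                      cancer_gene = logical(), ccf_a = numeric(),
                      ci_low_a = numeric(), ci_high_a = numeric(),
                      ccf_b = numeric(), ci_low_b = numeric(),
                      ci_high_b = numeric(), category = character(),
                      stringsAsFactors = FALSE)
  out
}

.cn_state <- function(total_cn, minor_cn) {
  ifelse(total_cn == 0, "homdel",
  ifelse(total_cn > 2, "gain",
  ifelse(total_cn < 2, "loss",
  ifelse(minor_cn == 0, "cnloh", "neutral"))))
}

.check_segmentation <- function(seg, label) {
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping segments within sample ", label,
           " on chromosome ", ch, ": input must be a segmentation")
  }
  invisible(TRUE)
}

#' Match and classify copy-number segments across a biopsy pair
#'
#' Aberrant segments (gain, loss, copy-neutral LOH) are matched across the
#' pair when they lie on the same chromosome, share the copy-number state
#' class and overlap reciprocally by at least `min_overlap`. Matched segments
#' are shared, unmatched private. A CNV call is subclonal when its CCF
#' (cellular fraction over purity) is below 0.5 — in both sites for shared
#' events, in the observed site for private ones; no confidence-interval rule
#' applies to CNVs. Homozygous deletions are reported separately.
#'
#' @param segments_a,segments_b segment tables with columns `chrom`, `start`,
#'   `end`, `total_cn`, `major_cn`, `minor_cn`, `cellular_fraction`.
#' @param purity_a,purity_b tumor purities.
#' @param min_overlap reciprocal-overlap fraction required to match
#'   (default 0.5).
#' @param ccf_threshold subclonality cutoff (default 0.5).
#' @return list with `calls` (data.frame: chrom, intervals, state, per-site
#'   CCFs, category) and `homozygous_deletions`.
#' @export
match_and_classify_cnv <- function(segments_a, segments_b,
                                   purity_a, purity_b,
                                   min_overlap = 0.5, ccf_threshold = 0.5) {
  .check_segmentation(segments_a, "A")
  .check_segmentation(segments_b, "B")
  prep <- function(seg, purity) {
    seg$state <- .cn_state(seg$total_cn, seg$minor_cn)
    seg$ccf <- suppressWarnings(cnv_ccf(seg$cellular_fraction, purity))
    seg
  }
  sa <- prep(segments_a, purity_a)
  sb <- prep(segments_b, purity_b)
  homdel <- rbind(
    if (any(sa$state == "homdel"))
      cbind(site = "A", sa[sa$state == "homdel", , drop = FALSE]),
    if (any(sb$state == "homdel"))
      cbind(site = "B", sb[sb$state == "homdel", , drop = FALSE]))
  sa <- sa[sa$state %in% c("gain", "loss", "cnloh"), , drop = FALSE]
  sb <- sb[sb$state %in% c("gain", "loss", "cnloh"), , drop = FALSE]

  used_b <- rep(FALSE, nrow(sb))
  calls <- list()
  add_call <- function(chrom, start, end, state, ccf_a, ccf_b) {
    shared <- !is.na(ccf_a) && !is.na(ccf_b)
    sub <- if (shared) ccf_a < ccf_threshold && ccf_b < ccf_threshold
           else (if (is.na(ccf_a)) ccf_b else ccf_a) < ccf_threshold
    category <- paste0(if (sub) "subclonal_" else "clonal_",
                       if (shared) "shared" else "private")
    data.frame(chrom = chrom, start = start, end = end, state = state,
               ccf_a = ccf_a, ccf_b = ccf_b, category = category,
               stringsAsFactors = FALSE)
  }
  if (nrow(sa)) for (i in seq_len(nrow(sa))) {
    a <- sa[i, ]
    len_a <- a$end - a$start + 1
    match_j <- NA_integer_
    if (nrow(sb)) for (j in seq_len(nrow(sb))) {
      if (used_b[j]) next
      b <- sb[j, ]
      if (b$chrom != a$chrom || b$state != a$state) next
      ov <- min(a$end, b$end) - max(a$start, b$start) + 1
      len_b <- b$end - b$start + 1
      if (ov >= min_overlap * len_a && ov >= min_overlap * len_b) {
        match_j <- j
        break
      }
    }
    if (!is.na(match_j)) {
      used_b[match_j] <- TRUE
      calls[[length(calls) + 1L]] <-
        add_call(a$chrom, a$start, a$end, a$state, a$ccf, sb$ccf[match_j])
    } else {
      calls[[length(calls) + 1L]] <-
        add_call(a$chrom, a$start, a$end, a$state, a$ccf, NA_real_)
    }
  }
  if (nrow(sb)) for (j in which(!used_b)) {
    b <- sb[j, ]
    calls[[length(calls) + 1L]] <-
      add_call(b$chrom, b$start, b$end, b$state, NA_real_, b$ccf)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               state = character(), ccf_a = numeric(), ccf_b = numeric(),
               category = character(), stringsAsFactors = FALSE)
  list(calls = calls, homozygous_deletions = homdel)
}

#' Detect a shared subclonal population (polyclonal dissemination signal)
#'
#' Flags a patient pair when at least `min_variants` variants are classified
#' subclonal-shared, i.e. a tumor cell population below clonality in both
#' biopsies — the genomic signature of polyclonal dissemination through the
#' pleural cavity.
#'
#' @param calls clonality-call data.frame from [pair_clonality()].
#' @param cnv_calls optional CNV call data.frame from
#'   [match_and_classify_cnv()] used as corroborating evidence.
#' @param min_variants minimum supporting variants (default 2).
#' @return list: `flag`, `n_support`, `supporting_variants` (keys),
#'   `cancer_genes` among supporters, `cnv_corroborated`.
#' @export
detect_shared_subclone <- function(calls, cnv_calls = NULL, min_variants = 2) {
  sup <- calls[calls$category == "subclonal_shared", , drop = FALSE]
  cg <- if ("cancer_gene" %in% names(sup))
    unique(sup$gene[sup$cancer_gene & !is.na(sup$gene)]) else character()
  cnv_ok <- !is.null(cnv_calls) && nrow(cnv_calls) > 0 &&
    any(cnv_calls$category == "subclonal_shared")
  list(flag = nrow(sup) >= min_variants,
       n_support = nrow(sup),
       supporting_variants = sup$key,
       cancer_genes = cg,
       cnv_corroborated = cnv_ok)
}

#' Build the schematic clonal tree of a biopsy pair
#'
#' Summarizes clonality calls as the conventional schematic tree: the trunk
#' holds all clonal-shared variants; a shared subclone node (present in both
#' biopsies) holds the subclonal-shared variants; per-site branches hold
#' clonal-private variants, with subclonal-private leaves below them. Node
#' variant counts drive line width in downstream drawings.
#'
#' @param calls clonality-call data.frame from [pair_clonality()]; if a
#'   `patient` column is present it must contain a single patient.
#' @return list of nodes (`id`, `parent`, `sites`, `n_variants`,
#'   `variants`), class `"clonal_tree"`. Nodes with zero variants are kept
#'   only for the trunk.
#' @export
build_clonal_tree <- function(calls) {
  if ("patient" %in% names(calls) && length(unique(calls$patient)) > 1)
    stop("calls from more than one patient; build one tree per patient")
  pick <- function(cat) calls$key[calls$category == cat]
  nodes <- list(list(id = "trunk", parent = NA_character_,
                     sites = c("A", "B"),
                     n_variants = length(pick("clonal_shared")),
                     variants = pick("clonal_shared")))
  add <- function(nodes, id, parent, sites, keys) {
    if (!length(keys)) return(nodes)
    c(nodes, list(list(id = id, parent = parent, sites = sites,
                       n_variants = length(keys), variants = keys)))
  }
  nodes <- add(nodes, "shared_subclone", "trunk", c("A", "B"),
               pick("subclonal_shared"))
  priv <- calls[calls$category %in%
                  c("clonal_private", "subclonal_private"), , drop = FALSE]
  for (site in c("A", "B")) {
    ccf_here <- if (site == "A") priv$ccf_a else priv$ccf_b
    here <- priv[!is.na(ccf_here), , drop = FALSE]
    cl <- here$key[here$category == "clonal_private"]
    sc <- here$key[here$category == "subclonal_private"]
    branch_id <- paste0("private_", site)
    if (length(cl)) {
      nodes <- add(nodes, branch_id, "trunk", site, cl)
      nodes <- add(nodes, paste0("subclonal_", site), branch_id, site, sc)
    } else {
      nodes <- add(nodes, paste0("subclonal_", site), "trunk", site, sc)
    }
  }
  structure(nodes, class = "clonal_tree")
}

#' @export
print.clonal_tree <- function(x, ...) {
  cat("Clonal tree with", length(x), "node(s)\n")
  for (nd in x)
    cat(sprintf("  %-18s parent=%-16s sites=%-3s n=%d\n", nd$id,
                ifelse(is.na(nd$parent), "-", nd$parent),
                paste(nd$sites, collapse = ""), nd$n_variants))
  invisible(x)
}

#' Multi-section VAF profile of a query variant against a clonal anchor
#'
#' Descriptive profile of a putatively subclonal variant across many physical
#' sections of one sample: per-section VAFs of the query and of a clonal
#' anchor variant, the fraction of sections where the query is detected
#' (VAF > 0 with at least `min_alt` supporting reads), and the median
#' query/anchor VAF ratio. A query found in a subset of sections at a
#' consistent fraction of the anchor VAF confirms subclonal status.
#'
#' @param sections data.frame with columns `section`, `query_alt`,
#'   `query_depth`, `anchor_alt`, `anchor_depth`.
#' @param min_alt minimum alt reads to count the query as detected
#'   (default 2).
#' @return list: `table` (per-section VAFs and ratio), `detection_fraction`,
#'   `median_ratio` (over sections where the anchor is observed).
#' @export
section_vaf_profile <- function(sections, min_alt = 2) {
  zero <- sections$query_depth == 0 | sections$anchor_depth == 0
  if (any(zero)) {
    warning(sum(zero), " section(s) with zero depth excluded")
    sections <- sections[!zero, , drop = FALSE]
  }
  if (!nrow(sections)) stop("no usable sections")
  qv <- sections$query_alt / sections$query_depth
  av <- sections$anchor_alt / sections$anchor_depth
  detected <- qv > 0 & sections$query_alt >= min_alt
  ratio <- ifelse(av > 0, qv / av, NA_real_)
  # the ratio summarizes the sections where the query is seen at all;
  # undetected sections contribute to the detection fraction instead
  med <- if (any(detected)) stats::median(ratio[detected], na.rm = TRUE)
         else NA_real_
  list(
    table = data.frame(section = sections$section, query_vaf = qv,
                       anchor_vaf = av, ratio = ratio, detected = detected),
    detection_fraction = mean(detected),
    median_ratio = med
  )
}
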