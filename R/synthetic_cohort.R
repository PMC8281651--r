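#' Simulate the clonal structure of a two-site tumor
#'
#' Draws a clone tree (a trunk clone plus optional subclones descending from
#' it) and the composition of two biopsies (sites A and B) from that tumor.
#' Scenarios control the spatial segregation of subclones:
#' `"private_subclones"` places every subclone in exactly one site,
#' `"shared_subclone"` places every subclone in both sites at a fraction
#' below 0.5 (the polyclonal-dissemination configuration), and `"mixed"`
#' draws each subclone as shared or private at random. Trunk mutations have
#' true CCF 1 at both sites by construction.
#'
#' @param n_trunk_mut number of trunk (clonal shared) mutations, >= 1.
#' @param n_subclones number of subclones descending from the trunk.
#' @param muts_per_subclone private mutations per subclone.
#' @param scenario one of `"mixed"`, `"private_subclones"`,
#'   `"shared_subclone"`.
#' @param seed integer seed; output is deterministic given the seed.
#' @param purity_range range the two biopsy purities are drawn from
#'   (default 0.3-0.9, reflecting the purity spread of surgical biopsies).
#' @param purity optional length-2 vector fixing the purities of sites A
#'   and B.
#' @return object of class `"clone_sim"`: `tree` (list of clone records with
#'   `id`, `parent`, `mutations`), `compositions` (per-site clone fractions
#'   and purity), `mutations` (data.frame of coordinates, gene and
#'   pathogenicity annotations) and `truth` (per-site true CCF and the true
#'   four-way category of every mutation).
#' @export
simulate_clone_structure <- function(n_trunk_mut, n_subclones = 0,
                                     muts_per_subclone = 0,
                                     scenario = c("mixed",
                                                  "private_subclones",
                                                  "shared_subclone"),
                                     seed = 1,
                                     purity_range = c(0.3, 0.9),
                                     purity = NULL) {
  scenario <- match.arg(scenario)
  if (n_trunk_mut < 1) stop("n_trunk_mut must be >= 1")
  if (n_subclones < 0 || muts_per_subclone < 0)
    stop("counts must be non-negative")
  if (scenario == "shared_subclone" && n_subclones < 1)
    stop("shared_subclone scenario requires n_subclones >= 1")
  set.seed(seed)

  n_mut <- n_trunk_mut + n_subclones * muts_per_subclone
  mut_ids <- sprintf("M%04d", seq_len(max(n_mut, 1)))
  clone_ids <- c("trunk",
                 if (n_subclones > 0) sprintf("sub%02d", seq_len(n_subclones)))
  trunk_muts <- mut_ids[seq_len(n_trunk_mut)]
  tree <- list(list(id = "trunk", parent = NA_character_,
                    mutations = trunk_muts))
  mut_clone <- stats::setNames(rep("trunk", n_trunk_mut), trunk_muts)
  if (n_subclones > 0) for (k in seq_len(n_subclones)) {
    own <- if (muts_per_subclone > 0)
      mut_ids[n_trunk_mut + (k - 1) * muts_per_subclone +
                seq_len(muts_per_subclone)] else character()
    tree[[k + 1L]] <- list(id = clone_ids[k + 1L], parent = "trunk",
                           mutations = own)
    mut_clone[own] <- clone_ids[k + 1L]
  }

  # per-site fraction of cells belonging (exclusively) to each subclone
  frac <- matrix(0, nrow = n_subclones, ncol = 2,
                 dimnames = list(clone_ids[-1], c("A", "B")))
  if (n_subclones > 0) {
    kind <- switch(scenario,
      shared_subclone = rep("shared", n_subclones),
      private_subclones = rep("private", n_subclones),
      mixed = sample(c("shared", "private"), n_subclones, replace = TRUE))
    priv_site <- sample(1:2, n_subclones, replace = TRUE)
    for (k in seq_len(n_subclones)) {
      if (kind[k] == "shared") {
        frac[k, ] <- stats::runif(2, 0.08, 0.45)
      } else {
        hi <- if (scenario == "mixed") 0.85 else 0.45
        frac[k, priv_site[k]] <- stats::runif(1, 0.1, hi)
      }
    }
    # siblings share the tumor with the trunk-only population
    for (s in 1:2) {
      tot <- sum(frac[, s])
      if (tot > 0.9) frac[, s] <- frac[, s] * 0.9 / tot
    }
  }

  if (is.null(purity)) purity <- stats::runif(2, purity_range[1],
                                              purity_range[2])
  compositions <- lapply(1:2, function(s) {
    cf <- c(trunk = 1 - sum(frac[, s]), frac[, s])
    names(cf) <- clone_ids
    list(site_id = c("A", "B")[s], clone_fractions = cf, purity = purity[s])
  })
  names(compositions) <- c("A", "B")

  # true CCF at a site = sum of fractions of clones carrying the mutation;
  # subclone cells also carry all trunk mutations
  ccf <- matrix(0, nrow = n_mut, ncol = 2,
                dimnames = list(mut_ids, c("A", "B")))
  for (m in mut_ids) {
    cl <- mut_clone[[m]]
    ccf[m, ] <- if (cl == "trunk") 1 else frac[cl, ]
  }
  category <- apply(ccf, 1, function(x) {
    shared <- all(x > 0)
    obs <- x[x > 0]
    sub <- all(obs < 0.5)
    paste0(if (sub) "subclonal_" else "clonal_",
           if (shared) "shared" else "private")
  })

  muts <- data.frame(
    mutation = mut_ids,
    clone = unname(mut_clone[mut_ids]),
    chrom = paste0("chr", 1 + (seq_len(n_mut) - 1) %% 22),
    pos = 1e6 + 1000 * seq_len(n_mut),
    ref = sample(c("A", "C", "G", "T"), n_mut, replace = TRUE),
    gene = sprintf("GENE%04d", seq_len(n_mut)),
    stringsAsFactors = FALSE
  )
  muts$alt <- vapply(muts$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  # the first mutation of each clone plays the cancer-gene role (NF2-like)
  muts$cancer_gene <- !duplicated(muts$clone)
  muts$sift <- ifelse(muts$cancer_gene, "deleterious",
                      sample(c("deleterious", "tolerated", "unknown"), n_mut,
                             replace = TRUE, prob = c(0.4, 0.5, 0.1)))
  muts$polyphen <- ifelse(muts$cancer_gene, "probably_damaging",
                          sample(c("probably_damaging", "possibly_damaging",
                                   "benign", "unknown"), n_mut,
                                 replace = TRUE))
  muts$consequence <- "missense_variant"

  structure(list(tree = tree, compositions = compositions, mutations = muts,
                 truth = list(ccf = ccf, category = category,
                              scenario = scenario)),
            class = "clone_sim")
}

#' Simulate sequencing reads for every mutation of a simulated tumor
#'
#' Applies the binomial read model: at each site, a mutation with true CCF
#' \eqn{f}, multiplicity 1 on a diploid background and biopsy purity \eqn{p}
#' has expected VAF \eqn{f p / (p \cdot 2 + (1-p) \cdot 2) = f p / 2}.
#' Depth is Poisson around `mean_depth`, floored at 20; the alt count is
#' binomial at the expected VAF. Mutations drawing zero alt reads are emitted
#' as absent (not called) at that site, as are mutations with true CCF 0.
#'
#' @param sim a `"clone_sim"` object from [simulate_clone_structure()].
#' @param mean_depth mean sequencing depth, >= 20.
#' @param seed integer seed.
#' @return list with elements `A` and `B`, each a variant observation
#'   data.frame (`sample_id`, `chrom`, `pos`, `ref`, `alt`, `alt_count`,
#'   `depth`, `gene`, `consequence`, `sift`, `polyphen`, `cancer_gene`,
#'   `mutation`).
#' @export
simulate_variant_reads <- function(sim, mean_depth = 100, seed = 1) {
  stopifnot(inherits(sim, "clone_sim"))
  if (mean_depth < 20) stop("mean_depth must be >= 20")
  set.seed(seed)
  out <- lapply(c("A", "B"), function(s) {
    p <- sim$compositions[[s]]$purity
    f <- sim$truth$ccf[, s]
    present <- f > 0
    m <- sim$mutations[present, , drop = FALSE]
    nr <- nrow(m)
    depth <- pmax(stats::rpois(nr, mean_depth), 20L)
    evaf <- f[present] * 1 * p / (p * 2 + (1 - p) * 2)
    alt <- stats::rbinom(nr, depth, evaf)
    keep <- alt > 0
    data.frame(sample_id = paste0("S", s),
               chrom = m$chrom, pos = m$pos, ref = m$ref, alt = m$alt,
               alt_count = alt, depth = depth,
               gene = m$gene, consequence = m$consequence,
               sift = m$sift, polyphen = m$polyphen,
               cancer_gene = m$cancer_gene, mutation = m$mutation,
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  })
  names(out) <- c("A", "B")
  out
}

#' Build reference epithelioid/sarcomatoid expression profiles
#'
#' Constructs two synthetic reference transcriptome profiles over a gene
#' universe: a shared baseline plus component-specific marker genes elevated
#' in exactly one profile. These stand in for the epithelioid-like and
#' sarcomatoid-like reference transcriptomes used by histo-molecular
#' deconvolution; they are synthetic and carry no biological content.
#'
#' @param genes character vector, the gene universe.
#' @param n_markers markers elevated per component.
#' @param effect log2-scale elevation of marker genes.
#' @param seed integer seed.
#' @return matrix `length(genes) x 2` with columns `E` and `S`; marker genes
#'   recorded in attributes `e_markers` / `s_markers`.
#' @export
make_es_profiles <- function(genes, n_markers = 100, effect = 3, seed = 1) {
  set.seed(seed)
  base <- stats::runif(length(genes), 2, 8)
  prof <- cbind(E = base, S = base)
  rownames(prof) <- genes
  idx <- sample(length(genes), 2 * n_markers)
  e_idx <- idx[seq_len(n_markers)]
  s_idx <- idx[n_markers + seq_len(n_markers)]
  prof[e_idx, "E"] <- prof[e_idx, "E"] + effect
  prof[s_idx, "S"] <- prof[s_idx, "S"] + effect
  attr(prof, "e_markers") <- genes[e_idx]
  attr(prof, "s_markers") <- genes[s_idx]
  prof
}

#' Build synthetic immune/stromal marker signatures
#'
#' Assigns disjoint marker-gene sets to a number of cell populations, drawn
#' from genes not already used as E/S markers. Purely synthetic stand-ins for
#' curated population signatures.
#'
#' @param genes gene universe.
#' @param exclude genes not eligible as markers (e.g. E/S markers).
#' @param n_populations number of cell populations.
#' @param genes_per_pop markers per population.
#' @param seed integer seed.
#' @return named list of marker-gene character vectors.
#' @export
make_immune_signatures <- function(genes, exclude = character(),
                                   n_populations = 8, genes_per_pop = 10,
                                   seed = 1) {
  set.seed(seed)
  pool <- setdiff(genes, exclude)
  need <- n_populations * genes_per_pop
  if (length(pool) < need)
    stop("gene universe too small for the requested signatures")
  picked <- sample(pool, need)
  sig <- split(picked, rep(seq_len(n_populations), each = genes_per_pop))
  names(sig) <- sprintf("population_%02d", seq_len(n_populations))
  sig
}

#' Simulate a paired expression matrix for a two-site tumor
#'
#' Variance-stabilized (VST, log2-like) expression at each site is the E/S
#' mixture of the two reference profiles, plus additive immune-population
#' components over the population marker genes, plus Gaussian noise; a
#' designated set of genes receives an extra per-site shift to act as true
#' differentially expressed (DE) genes. FPKM is linked to the VST scale as
#' \eqn{2^v - 1} (floored at 0), so the FPKM < 1 filter corresponds to
#' VST < 1.
#'
#' @param sim a `"clone_sim"` object (used for site naming only).
#' @param n_genes gene-universe size when profiles are auto-generated.
#' @param es_profiles matrix from [make_es_profiles()] (auto-generated when
#'   `NULL`).
#' @param immune_signatures list from [make_immune_signatures()]
#'   (auto-generated when `NULL`).
#' @param es_scores 2x2 matrix of true (e, s) scores per site, rows A and B;
#'   drawn when `NULL` (e uniform on 0.3-0.95, site delta sd 0.1).
#' @param immune_abundance populations x 2 matrix of true abundances
#'   (log2-scale additive components); drawn uniform on 0.5-2 when `NULL`.
#' @param n_de number of true DE genes.
#' @param de_shift VST shift applied (with random sign) to site A for each
#'   true DE gene; must exceed 1 for the DE rule to recover them at noise 0.
#' @param noise_sd Gaussian noise sd on the VST scale.
#' @param seed integer seed.
#' @return list: `genes`, `vst` and `fpkm` (genes x 2 matrices, columns A/B),
#'   `es_scores`, `immune_abundance`, `de_truth` (gene, sign of VST_A -
#'   VST_B), `es_profiles`, `immune_signatures`.
#' @export
simulate_expression_pair <- function(sim, n_genes = 1000, es_profiles = NULL,
                                     immune_signatures = NULL,
                                     es_scores = NULL,
                                     immune_abundance = NULL,
                                     n_de = 50, de_shift = 1.5,
                                     noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  if (is.null(es_profiles)) {
    # marker-set sizes scale down with small simulated universes
    n_markers <- max(5L, min(100L, n_genes %/% 6L))
    es_profiles <- make_es_profiles(sprintf("GENE%04d", seq_len(n_genes)),
                                    n_markers = n_markers, seed = seed)
  }
  genes <- rownames(es_profiles)
  if (is.null(immune_signatures)) {
    n_free <- length(genes) - length(attr(es_profiles, "e_markers")) -
      length(attr(es_profiles, "s_markers"))
    immune_signatures <- make_immune_signatures(
      genes, exclude = c(attr(es_profiles, "e_markers"),
                         attr(es_profiles, "s_markers")),
      genes_per_pop = max(2L, min(10L, n_free %/% 16L)), seed = seed)
  }
  missing <- setdiff(unlist(immune_signatures), genes)
  if (length(missing))
    stop("signature gene(s) absent from the gene universe: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (is.null(es_scores)) {
    e_a <- stats::runif(1, 0.3, 0.95)
    e_b <- min(max(e_a + stats::rnorm(1, 0, 0.1), 0.05), 1)
    es_scores <- rbind(A = c(e = e_a, s = 1 - e_a),
                       B = c(e = e_b, s = 1 - e_b))
  }
  pops <- names(immune_signatures)
  if (is.null(immune_abundance)) {
    immune_abundance <- matrix(stats::runif(2 * length(pops), 0.5, 2),
                               ncol = 2, dimnames = list(pops, c("A", "B")))
  }
  vst <- sapply(c("A", "B"), function(s) {
    v <- es_scores[s, "e"] * es_profiles[, "E"] +
      es_scores[s, "s"] * es_profiles[, "S"]
    for (p in pops) {
      idx <- match(immune_signatures[[p]], genes)
      v[idx] <- v[idx] + immune_abundance[p, s]
    }
    v
  })
  rownames(vst) <- genes
  de_truth <- data.frame(gene = character(), sign = integer())
  if (n_de > 0) {
    de_genes <- sample(genes, n_de)
    sgn <- sample(c(-1L, 1L), n_de, replace = TRUE)
    vst[match(de_genes, genes), "A"] <-
      vst[match(de_genes, genes), "A"] + sgn * de_shift
    de_truth <- data.frame(gene = de_genes, sign = sgn,
                           stringsAsFactors = FALSE)
  }
  if (noise_sd > 0)
    vst <- vst + matrix(stats::rnorm(length(vst), 0, noise_sd), nrow(vst))
  fpkm <- pmax(2^vst - 1, 0)
  list(genes = genes, vst = vst, fpkm = fpkm, es_scores = es_scores,
       immune_abundance = immune_abundance, de_truth = de_truth,
       es_profiles = es_profiles, immune_signatures = immune_signatures)
}

#' Simulate a paired methylation matrix for a two-site tumor
#'
#' Baseline beta-values are drawn from a bimodal Beta mixture (mostly
#' unmethylated or mostly methylated CpGs, as on methylation arrays); a
#' designated set of CpGs is shifted by +/- `delta` in site B (clipped to
#' \[0, 1\]) to act as true differentially methylated (DM) loci. Detection
#' p-values are small except for a configurable failed fraction.
#'
#' @param sim a `"clone_sim"` object (site naming only).
#' @param n_cpg number of CpGs.
#' @param n_dm number of true DM CpGs (<= `n_cpg`).
#' @param delta beta shift of true DM CpGs; must be >= 0.2 for the DM rule
#'   to recover them at noise 0, and within \[0, 1\].
#' @param noise_sd sd of Gaussian beta noise (clipped), default 0.
#' @param fail_fraction fraction of CpG/sample detection p-values drawn
#'   from the failed range (>= 0.05).
#' @param genes optional gene universe for the CpG-to-gene annotation;
#'   CpGs are mapped round-robin, with ~10\% left unannotated.
#' @param seed integer seed.
#' @return list: `cpg`, `beta` and `detp` (n_cpg x 2 matrices, columns A/B),
#'   `annotation` (cpg, gene), `dm_truth` (cpg, direction of B - A).
#' @export
simulate_methylation_pair <- function(sim, n_cpg = 2000, n_dm = 100,
                                      delta = 0.3, noise_sd = 0,
                                      fail_fraction = 0, genes = NULL,
                                      seed = 1) {
  if (n_dm > n_cpg) stop("n_dm must be <= n_cpg")
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]")
  set.seed(seed)
  cpg <- sprintf("cg%08d", seq_len(n_cpg))
  lowhigh <- stats::runif(n_cpg) < 0.5
  base <- ifelse(lowhigh, stats::rbeta(n_cpg, 2, 10),
                 stats::rbeta(n_cpg, 10, 2))
  beta <- cbind(A = base, B = base)
  dm_truth <- data.frame(cpg = character(), direction = integer())
  if (n_dm > 0) {
    dm_idx <- sample(n_cpg, n_dm)
    # shift toward the free end so the clip cannot shrink the difference
    dir <- ifelse(base[dm_idx] > 0.5, -1L, 1L)
    beta[dm_idx, "B"] <- pmin(pmax(base[dm_idx] + dir * delta, 0), 1)
    dm_truth <- data.frame(cpg = cpg[dm_idx], direction = dir,
                           stringsAsFactors = FALSE)
  }
  if (noise_sd > 0)
    beta <- pmin(pmax(beta + matrix(stats::rnorm(length(beta), 0, noise_sd),
                                    nrow(beta)), 0), 1)
  rownames(beta) <- cpg
  detp <- matrix(stats::runif(2 * n_cpg, 0, 0.04), ncol = 2,
                 dimnames = list(cpg, c("A", "B")))
  if (fail_fraction > 0) {
    fail <- stats::runif(2 * n_cpg) < fail_fraction
    detp[fail] <- stats::runif(sum(fail), 0.05, 0.6)
  }
  if (is.null(genes)) genes <- sprintf("GENE%04d", seq_len(max(n_cpg %/% 2, 1)))
  gene_map <- rep_len(genes, n_cpg)
  unann <- stats::runif(n_cpg) < 0.1
  annotation <- data.frame(cpg = cpg,
                           gene = ifelse(unann, NA_character_, gene_map),
                           stringsAsFactors = FALSE)
  list(cpg = cpg, beta = beta, detp = detp, annotation = annotation,
       dm_truth = dm_truth)
}

#' Simulate a complete multi-site tumor cohort
#'
#' Generates `n_patients` two-biopsy tumors sharing one gene universe, one
#' pair of E/S reference profiles and one immune signature set, so that
#' cohort-level operations (clustering, hot/cold assignment, per-dataset
#' standardization) are exercised on commensurable matrices. Half of the
#' patients (rounded up) carry a hot immune profile (+`hot_shift` on every
#' population component at both sites); optionally one patient is planted as
#' a mixed pair (hot at site A, cold at site B). Scenarios for the clonal
#' structure cycle through the supplied list.
#'
#' @param n_patients number of patients (two biopsies each).
#' @param scenarios character vector recycled over patients.
#' @param n_trunk_mut,n_subclones,muts_per_subclone clone-structure sizes.
#' @param mean_depth sequencing depth.
#' @param n_genes,n_cpg,n_de,n_dm omics universe sizes and planted truths.
#' @param de_shift,dm_delta,noise_sd planted effect sizes and expression
#'   noise.
#' @param purity_range biopsy purity range.
#' @param hot_shift additive immune component of hot samples (log2 scale).
#' @param mixed_pair_patient index of the patient planted as a hot/cold
#'   mixed pair, or `NULL` for none.
#' @param seed integer seed.
#' @return object of class `"synthetic_cohort"`: per-patient list entries
#'   (`clone_sim`, `reads`, `expression`, `methylation`), shared
#'   `es_profiles`, `immune_signatures`, `genes`, and a `truth` summary
#'   (hot/cold status per sample, mixed patient, scenarios).
#' @export
simulate_cohort <- function(n_patients = 8,
                            scenarios = c("mixed", "shared_subclone",
                                          "private_subclones"),
                            n_trunk_mut = 20, n_subclones = 2,
                            muts_per_subclone = 5,
                            mean_depth = 150,
                            n_genes = 1200, n_cpg = 1500,
                            n_de = 60, n_dm = 80,
                            de_shift = 1.8, dm_delta = 0.3, noise_sd = 0.2,
                            purity_range = c(0.3, 0.9),
                            hot_shift = 2, mixed_pair_patient = NULL,
                            seed = 1) {
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  es_profiles <- make_es_profiles(genes, seed = seed)
  immune_signatures <- make_immune_signatures(
    genes, exclude = c(attr(es_profiles, "e_markers"),
                       attr(es_profiles, "s_markers")), seed = seed)
  pops <- names(immune_signatures)
  n_hot <- ceiling(n_patients / 2)
  hot_patient <- rep(c(TRUE, FALSE), length.out = n_patients)

  patients <- vector("list", n_patients)
  names(patients) <- sprintf("P%02d", seq_len(n_patients))
  hot_status <- list()
  for (i in seq_len(n_patients)) {
    pseed <- seed * 1000L + i
    scen <- scenarios[1 + (i - 1) %% length(scenarios)]
    cs <- simulate_clone_structure(n_trunk_mut, n_subclones,
                                   muts_per_subclone, scenario = scen,
                                   seed = pseed, purity_range = purity_range)
    reads <- simulate_variant_reads(cs, mean_depth = mean_depth,
                                    seed = pseed + 1L)
    set.seed(pseed + 2L)
    hot_sites <- if (!is.null(mixed_pair_patient) &&
                     i == mixed_pair_patient) c(TRUE, FALSE)
      else rep(hot_patient[i], 2)
    base_ab <- matrix(stats::runif(2 * length(pops), 0.2, 0.8), ncol = 2,
                      dimnames = list(pops, c("A", "B")))
    base_ab[, 1] <- base_ab[, 1] + if (hot_sites[1]) hot_shift else 0
    base_ab[, 2] <- base_ab[, 2] + if (hot_sites[2]) hot_shift else 0
    expr <- simulate_expression_pair(cs, es_profiles = es_profiles,
                                     immune_signatures = immune_signatures,
                                     immune_abundance = base_ab,
                                     n_de = n_de, de_shift = de_shift,
                                     noise_sd = noise_sd, seed = pseed + 3L)
    meth <- simulate_methylation_pair(cs, n_cpg = n_cpg, n_dm = n_dm,
                                      delta = dm_delta, genes = genes,
                                      seed = pseed + 4L)
    patients[[i]] <- list(clone_sim = cs, reads = reads, expression = expr,
                          methylation = meth, scenario = scen)
    hot_status[[names(patients)[i]]] <- stats::setNames(
      ifelse(hot_sites, "hot", "cold"), c("A", "B"))
  }
  structure(list(patients = patients, genes = genes,
                 es_profiles = es_profiles,
                 immune_signatures = immune_signatures,
                 truth = list(hot_status = hot_status,
                              mixed_pair_patient = mixed_pair_patient,
                              scenarios = vapply(patients, `[[`,
                                                 character(1), "scenario"))),
            class = "synthetic_cohort")
}
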