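test_that("damaging consensus takes any one tool's damaging prediction", {
  expect_true(is_damaging("tolerated", "probably_damaging"))
  expect_true(is_damaging("deleterious", "unknown"))
  expect_true(is_damaging("tolerated", "possibly_damaging"))
  expect_false(is_damaging("tolerated", "benign"))
  expect_false(is_damaging("unknown", "unknown"))
  expect_false(is_damaging(NA, "benign"))
  expect_error(is_damaging("bad_label", "benign"), "accepted")
  expect_error(is_damaging("tolerated", "damaging"), "accepted")
})

test_that("CCF estimation matches the closed-form purity/CN correction", {
  # clonal het variant at purity 1
  e <- estimate_ccf(50, 100, purity = 1)
  expect_equal(e$ccf, 1)
  expect_equal(e$multiplicity, 1L)
  # purity-corrected: 0.3 * 2 / 0.6 = 1
  e <- estimate_ccf(30, 100, purity = 0.6)
  expect_equal(e$ccf, 1)
  # copy-number corrected: 0.1 * (0.8*3 + 0.2*2) / 0.8 = 0.35, mult 1
  e <- estimate_ccf(10, 100, purity = 0.8, total_cn = 3, major_cn = 2)
  expect_equal(e$ccf, 0.35)
  expect_equal(e$multiplicity, 1L)
  expect_error(estimate_ccf(10, 100, purity = 0), "purity")
  expect_error(estimate_ccf(10, 100, purity = 0.5, total_cn = 0),
               "zero copies")
})

test_that("diploid multiplicity-1 CCF equals 2*vaf/purity to 1e-12", {
  set.seed(42)
  for (i in 1:200) {
    depth <- sample(30:500, 1)
    alt <- sample.int(depth, 1)
    p <- runif(1, 0.1, 1)
    e <- estimate_ccf(alt, depth, purity = p, ccf_max = Inf)
    expect_equal(e$ccf_raw * e$multiplicity, 2 * (alt / depth) / p,
                 tolerance = 1e-12)
  }
})

test_that("CCF is strictly increasing in alt count before capping", {
  e <- estimate_ccf(1:99, 100, purity = 0.7, ccf_max = Inf)
  expect_true(all(diff(e$ccf_raw * e$multiplicity) > 0))
})

test_that("CCF interval is the transformed Clopper-Pearson interval", {
  # independent oracle: binom.test's exact interval, same transform
  set.seed(7)
  for (i in 1:25) {
    depth <- sample(50:300, 1)
    alt <- sample.int(depth - 1, 1)
    p <- runif(1, 0.3, 1)
    e <- estimate_ccf(alt, depth, purity = p, ccf_max = Inf)
    ci <- binom.test(alt, depth)$conf.int * 2 / p
    expect_equal(e$ci_low, ci[1], tolerance = 1e-9)
    expect_equal(e$ci_high, ci[2], tolerance = 1e-9)
  }
})

test_that("over-unity CCF estimates are capped but flagged", {
  e <- estimate_ccf(90, 100, purity = 0.6)  # raw 3.0 -> mult 3 capped at 1
  expect_true(all(e$ccf <= 1.5))
  e2 <- estimate_ccf(95, 100, purity = 0.5, ccf_max = 1.5)
  expect_true(e2$capped || e2$ccf <= 1.5)
  expect_true(e2$ccf_raw >= e2$ccf)
})

test_that("four-way clonality classification follows the CCF and CI rules", {
  expect_equal(classify_variant(ccf_row(1.0), ccf_row(0.98)),
               "clonal_shared")
  expect_equal(classify_variant(ccf_row(0.30, ci_high = 0.45),
                                ccf_row(0.25, ci_high = 0.40)),
               "subclonal_shared")
  expect_equal(classify_variant(ccf_row(0.9), NULL), "clonal_private")
  # CI rule failing in one sample blocks subclonality
  expect_equal(classify_variant(ccf_row(0.3, ci_high = 1.1),
                                ccf_row(0.3, ci_high = 0.4)),
               "clonal_shared")
  # thresholds are strict: CCF exactly 0.5 is clonal
  expect_equal(classify_variant(ccf_row(0.5, ci_high = 0.6), NULL),
               "clonal_private")
  expect_equal(classify_variant(ccf_row(0.3, ci_high = 0.4), NULL),
               "subclonal_private")
  expect_error(classify_variant(NULL, NULL), "absent")
})

test_that("CNV CCF is cellular fraction over purity, capped with warning", {
  expect_equal(cnv_ccf(0.42, 0.6), 0.7)
  expect_equal(cnv_ccf(0.6, 0.6), 1.0)
  expect_warning(x <- cnv_ccf(0.75, 0.6), "purity")
  expect_equal(x, 1.0)
  expect_error(cnv_ccf(0.5, 0), "purity")
})

test_that("CNV matching requires chromosome, state class and 50% overlap", {
  a <- seg_table(c("chr1", "chr2"), c(1, 1), c(100, 200), c(3, 1),
                 c(2, 1), c(1, 0), c(0.6, 0.6))
  res <- match_and_classify_cnv(a, a, 0.6, 0.6)
  expect_equal(nrow(res$calls), 2)
  expect_true(all(res$calls$category == "clonal_shared"))

  # gain only in A at low CCF
  b_empty <- seg_table(character(), integer(), integer(), integer(),
                       integer(), integer(), numeric())
  a2 <- seg_table("chr1", 1, 100, 3, 2, 1, 0.18)
  res2 <- match_and_classify_cnv(a2, b_empty, 0.6, 0.6)
  expect_equal(res2$calls$category, "subclonal_private")

  # same interval, opposite state class: two private calls
  b3 <- seg_table("chr1", 1, 100, 1, 1, 0, 0.6)
  res3 <- match_and_classify_cnv(a2, b3, 0.6, 0.6)
  expect_equal(nrow(res3$calls), 2)
  expect_true(all(grepl("private", res3$calls$category)))

  # overlapping segments in one sample are not a segmentation
  bad <- seg_table(c("chr1", "chr1"), c(1, 50), c(100, 150), c(3, 3),
                   c(2, 2), c(1, 1), c(0.6, 0.6))
  expect_error(match_and_classify_cnv(bad, b_empty, 0.6, 0.6),
               "segmentation")

  # homozygous deletions reported separately
  a4 <- seg_table("chr3", 1, 100, 0, 0, 0, 0.5)
  res4 <- match_and_classify_cnv(a4, b_empty, 0.6, 0.6)
  expect_equal(nrow(res4$calls), 0)
  expect_equal(nrow(res4$homozygous_deletions), 1)
})

test_that("shared-subclone detection applies the supporter threshold", {
  calls <- data.frame(
    key = sprintf("chr1:%d:A:T", 1:8),
    gene = c("NF2", sprintf("G%d", 2:8)),
    cancer_gene = c(TRUE, rep(FALSE, 7)),
    category = c(rep("subclonal_shared", 6), "clonal_shared",
                 "clonal_private"),
    stringsAsFactors = FALSE)
  d <- detect_shared_subclone(calls)
  expect_true(d$flag)
  expect_equal(d$n_support, 6)
  expect_equal(d$cancer_genes, "NF2")

  none <- calls[calls$category == "clonal_shared", ]
  expect_false(detect_shared_subclone(none)$flag)

  one <- calls[1, ]
  expect_false(detect_shared_subclone(one, min_variants = 2)$flag)
  expect_true(detect_shared_subclone(one, min_variants = 1)$flag)
})

test_that("clonal tree summarizes categories into the schematic nodes", {
  only_clonal <- data.frame(key = c("k1", "k2"), ccf_a = c(1, 1),
                            ccf_b = c(1, 1),
                            category = "clonal_shared",
                            stringsAsFactors = FALSE)
  tr <- build_clonal_tree(only_clonal)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$id, "trunk")
  expect_equal(tr[[1]]$n_variants, 2)

  # a pair with a 6-variant shared subclone
  cs <- simulate_clone_structure(10, 1, 6, scenario = "shared_subclone",
                                 seed = 7, purity = c(0.8, 0.8))
  rd <- simulate_variant_reads(cs, mean_depth = 600, seed = 7)
  calls <- pair_clonality(rd$A, rd$B, 0.8, 0.8)
  tr2 <- build_clonal_tree(calls)
  ids <- vapply(tr2, `[[`, character(1), "id")
  expect_true("shared_subclone" %in% ids)
  expect_equal(tr2[[which(ids == "shared_subclone")]]$n_variants, 6)

  two_pat <- cbind(only_clonal, patient = c("P1", "P2"))
  expect_error(build_clonal_tree(two_pat), "one patient")
})

test_that("section VAF profiling reports detection and anchor ratio", {
  s <- data.frame(section = 1:4, query_alt = c(10, 12, 9, 11),
                  query_depth = 100, anchor_alt = c(10, 12, 9, 11),
                  anchor_depth = 100)
  pr <- section_vaf_profile(s)
  expect_equal(pr$detection_fraction, 1)
  expect_equal(pr$median_ratio, 1)

  s$query_alt <- 0
  pr0 <- section_vaf_profile(s)
  expect_equal(pr0$detection_fraction, 0)

  # 34 sections, query in half of them at a third of the anchor VAF
  s34 <- data.frame(section = 1:34,
                    query_alt = rep(c(10L, 0L), 17),
                    query_depth = 300,
                    anchor_alt = 30L, anchor_depth = 300)
  pr34 <- section_vaf_profile(s34)
  expect_equal(pr34$detection_fraction, 0.5)
  expect_equal(pr34$median_ratio, 1 / 3, tolerance = 0.05)

  s$query_depth <- c(0, 100, 100, 100)
  expect_warning(section_vaf_profile(s), "zero depth")
})

test_that("every paired variant gets exactly one category", {
  cs <- simulate_clone_structure(30, 2, 5, scenario = "mixed", seed = 11,
                                 purity_range = c(0.5, 0.9))
  rd <- simulate_variant_reads(cs, mean_depth = 300, seed = 12)
  calls <- pair_clonality(rd$A, rd$B, cs$compositions$A$purity,
                          cs$compositions$B$purity)
  expect_true(all(calls$category %in%
                    c("clonal_shared", "subclonal_shared",
                      "clonal_private", "subclonal_private")))
  expect_equal(sum(table(calls$category)), nrow(calls))
  expect_equal(nrow(calls), length(union(
    paste(rd$A$chrom, rd$A$pos, rd$A$ref, rd$A$alt, sep = ":"),
    paste(rd$B$chrom, rd$B$pos, rd$B$ref, rd$B$alt, sep = ":"))))
})
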