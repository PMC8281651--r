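test_that("clone structure respects scenario geometry and CCF algebra", {
  # no subclones: single-clone tree, trunk fraction 1 at both sites
  cs0 <- simulate_clone_structure(6, 0, 0, seed = 1)
  expect_length(cs0$tree, 1)
  expect_equal(unname(cs0$compositions$A$clone_fractions["trunk"]), 1)
  expect_equal(unname(cs0$compositions$B$clone_fractions["trunk"]), 1)
  expect_true(all(cs0$truth$ccf == 1))

  # shared subclone below clonality at both sites
  cs1 <- simulate_clone_structure(6, 1, 6, scenario = "shared_subclone",
                                  seed = 7)
  f <- sapply(cs1$compositions, function(x) x$clone_fractions["sub01"])
  expect_true(all(f > 0 & f < 0.5))
  expect_equal(sum(cs1$truth$category == "subclonal_shared"), 6)

  # private subclones present at exactly one site
  cs2 <- simulate_clone_structure(6, 2, 3, scenario = "private_subclones",
                                  seed = 7)
  fr <- sapply(cs2$compositions, function(x) x$clone_fractions)
  for (cl in c("sub01", "sub02"))
    expect_equal(sum(fr[cl, ] == 0), 1)

  # fractions are probabilities and true CCF is the carrying-clone sum
  for (cs in list(cs0, cs1, cs2)) {
    for (s in c("A", "B")) {
      cf <- cs$compositions[[s]]$clone_fractions
      expect_equal(sum(cf), 1, tolerance = 1e-9)
      expect_true(all(cf >= 0))
      p <- cs$compositions[[s]]$purity
      expect_true(p > 0 && p <= 1)
    }
    trunk_muts <- cs$tree[[1]]$mutations
    expect_true(all(cs$truth$ccf[trunk_muts, ] == 1))
  }

  expect_error(simulate_clone_structure(0), "n_trunk_mut")
  expect_error(simulate_clone_structure(5, 0, 0,
                                        scenario = "shared_subclone"),
               "requires")
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_clone_structure(10, 2, 4, scenario = "mixed", seed = 3)
  b <- simulate_clone_structure(10, 2, 4, scenario = "mixed", seed = 3)
  expect_identical(a, b)
  expect_identical(simulate_variant_reads(a, 100, seed = 5),
                   simulate_variant_reads(b, 100, seed = 5))
  ea <- simulate_expression_pair(a, n_genes = 200, seed = 9)
  eb <- simulate_expression_pair(b, n_genes = 200, seed = 9)
  expect_identical(ea$vst, eb$vst)
  ma <- simulate_methylation_pair(a, n_cpg = 100, n_dm = 10, seed = 9)
  mb <- simulate_methylation_pair(b, n_cpg = 100, n_dm = 10, seed = 9)
  expect_identical(ma$beta, mb$beta)
})

test_that("read model hits the expected VAF", {
  # trunk variant, purity 1, diploid: expected VAF 0.5
  cs <- simulate_clone_structure(200, 0, 0, seed = 2, purity = c(1, 1))
  rd <- simulate_variant_reads(cs, mean_depth = 10000, seed = 3)
  expect_true(abs(mean(rd$A$alt_count / rd$A$depth) - 0.5) < 0.02)

  # subclonal CCF 0.3 at purity 0.6: expected VAF 0.3*0.6/2 = 0.09,
  # checked as the mean over ~1000 binomial draws
  vafs <- lapply(1:20, function(i) {
    cs1 <- simulate_clone_structure(1, 1, 50, scenario = "shared_subclone",
                                    seed = 2, purity = c(0.6, 0.6))
    cs1$truth$ccf[-1, ] <- 0.3  # pin the true CCF for the expectation check
    rd1 <- simulate_variant_reads(cs1, mean_depth = 1000, seed = 100 + i)
    sub <- rd1$A[rd1$A$mutation != "M0001", ]
    sub$alt_count / sub$depth
  })
  expect_equal(mean(unlist(vafs)), 0.09, tolerance = 0.005)

  # true CCF 0 at a site means the variant is absent there
  csp <- simulate_clone_structure(5, 2, 10,
                                  scenario = "private_subclones", seed = 4)
  rdp <- simulate_variant_reads(csp, mean_depth = 500, seed = 5)
  for (s in c("A", "B")) {
    absent <- rownames(csp$truth$ccf)[csp$truth$ccf[, s] == 0]
    expect_false(any(rdp[[s]]$mutation %in% absent))
  }
  expect_error(simulate_variant_reads(csp, mean_depth = 5), "mean_depth")
})

test_that("read model is calibrated within 3 standard errors", {
  cs <- simulate_clone_structure(1500, 0, 0, seed = 6, purity = c(0.7, 0.7))
  rd <- simulate_variant_reads(cs, mean_depth = 200, seed = 7)
  v <- rd$A
  evaf <- 1 * 0.7 / 2
  obs <- v$alt_count / v$depth
  se <- sqrt(mean(evaf * (1 - evaf) / v$depth) / nrow(v))
  expect_true(nrow(v) >= 1000)
  expect_lt(abs(mean(obs) - evaf), 3 * se)
})

test_that("expression simulator links VST, FPKM and planted DE genes", {
  cs <- simulate_clone_structure(5, 0, 0, seed = 1)
  es <- rbind(A = c(e = 0.6, s = 0.4), B = c(e = 0.6, s = 0.4))
  ab <- matrix(1, nrow = 8, ncol = 2,
               dimnames = list(sprintf("population_%02d", 1:8),
                               c("A", "B")))
  # no noise, equal mixtures, no DE: identical columns
  ex <- simulate_expression_pair(cs, n_genes = 500, es_scores = es,
                                 immune_abundance = ab, n_de = 0,
                                 noise_sd = 0, seed = 2)
  expect_identical(ex$vst[, "A"], ex$vst[, "B"])
  expect_true(all(ex$fpkm >= 0))
  expect_equal(ex$fpkm, pmax(2^ex$vst - 1, 0))

  # planted DE genes with shift 1.5 are recovered exactly at noise 0
  ex2 <- simulate_expression_pair(cs, n_genes = 500, es_scores = es,
                                  immune_abundance = ab, n_de = 25,
                                  de_shift = 1.5, noise_sd = 0, seed = 3)
  de <- call_de_genes(ex2$fpkm[, "A"], ex2$fpkm[, "B"],
                      ex2$vst[, "A"], ex2$vst[, "B"])
  expect_setequal(de$gene, ex2$de_truth$gene)
  expect_equal(de$sign[match(ex2$de_truth$gene, de$gene)],
               ex2$de_truth$sign)

  bad_sig <- list(pop1 = c("NOT_A_GENE"))
  expect_error(simulate_expression_pair(cs, n_genes = 100,
                                        immune_signatures = bad_sig,
                                        seed = 1),
               "absent from the gene universe")
})

test_that("methylation simulator plants recoverable DM CpGs", {
  cs <- simulate_clone_structure(5, 0, 0, seed = 1)
  m0 <- simulate_methylation_pair(cs, n_cpg = 300, n_dm = 0, seed = 4)
  dm0 <- call_dm_cpg(m0$beta[, "A"], m0$beta[, "B"],
                     m0$detp[, "A"], m0$detp[, "B"])
  expect_equal(nrow(dm0), 0)

  # a shift of exactly 0.2 is called ("at least 0.2")
  m1 <- simulate_methylation_pair(cs, n_cpg = 300, n_dm = 40, delta = 0.2,
                                  seed = 5)
  dm1 <- call_dm_cpg(m1$beta[, "A"], m1$beta[, "B"],
                     m1$detp[, "A"], m1$detp[, "B"])
  expect_setequal(dm1$cpg, m1$dm_truth$cpg)
  expect_true(all(m1$beta >= 0 & m1$beta <= 1))

  # total detection failure suppresses every call
  m2 <- simulate_methylation_pair(cs, n_cpg = 300, n_dm = 40, delta = 0.4,
                                  fail_fraction = 1, seed = 6)
  dm2 <- call_dm_cpg(m2$beta[, "A"], m2$beta[, "B"],
                     m2$detp[, "A"], m2$detp[, "B"])
  expect_equal(nrow(dm2), 0)

  expect_error(simulate_methylation_pair(cs, n_cpg = 10, n_dm = 20),
               "n_dm")
  expect_error(simulate_methylation_pair(cs, n_cpg = 10, n_dm = 2,
                                         delta = 1.5), "delta")
})
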