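# exact upper-tail hypergeometric by pmf summation
brute_hyper_p <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

test_that("GMT round-trips through write and read", {
  sets <- list(alpha = c("g1", "g2"), beta = c("g3", "g4", "g5"))
  path <- tempfile(fileext = ".gmt")
  on.exit(unlink(path))
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
})

test_that("ORA hypergeometric p matches exact pmf summation", {
  set.seed(41)
  for (rep in 1:30) {
    N <- sample(30:200, 1)
    universe <- sprintf("g%04d", 1:N)
    K <- sample(5:min(30, N), 1)
    n <- sample(5:min(50, N), 1)
    sets <- list(s = sample(universe, K))
    de <- sample(universe, n)
    res <- ora(de, sets, universe)
    k <- res$overlap
    expect_equal(res$p, brute_hyper_p(k, K, N, n), tolerance = 1e-12)
    expect_equal(res$gene_ratio, k / K)
  }
})

test_that("ORA handles degenerate queries and applies BH across sets", {
  universe <- sprintf("g%03d", 1:100)
  sets <- list(ten = universe[1:10], twenty = universe[11:30],
               five = universe[31:35])
  # spec-style worked case: universe 100, set 10, 20 DE, overlap 5
  de <- c(universe[1:5], universe[40:54])
  res <- ora(de, sets, universe)
  r <- res[res$set == "ten", ]
  expect_equal(r$overlap, 5)
  expect_equal(r$gene_ratio, 0.5)
  expect_equal(r$p, brute_hyper_p(5, 10, 100, 20), tolerance = 1e-12)

  # zero overlap is never significant
  res0 <- ora(universe[90:99], list(s = universe[1:10]), universe)
  expect_false(res0$significant)

  # query = universe: overlap = set size, p = 1
  resU <- ora(universe, sets, universe)
  expect_true(all(resU$overlap == resU$set_size))
  expect_true(all(resU$p == 1))
  expect_true(all(resU$gene_ratio == 1))

  # BH monotone in raw-p order and invariant to set ordering
  set.seed(42)
  sets2 <- lapply(1:12, function(i) sample(universe, sample(5:20, 1)))
  names(sets2) <- sprintf("set%02d", 1:12)
  de2 <- sample(universe, 25)
  a <- ora(de2, sets2, universe)
  expect_true(all(diff(a$fdr[order(a$p)]) >= -1e-15))
  expect_true(all(a$fdr >= a$p - 1e-15))
  b <- ora(de2, rev(sets2), universe)
  expect_equal(a[order(a$set), c("p", "fdr", "significant")],
               b[order(b$set), c("p", "fdr", "significant")],
               ignore_attr = TRUE)

  expect_error(ora(de2, sets2, character()), "universe")
  expect_warning(ora(c(de2, "NOT_THERE"), sets2, universe), "dropped")
})

test_that("ssGSEA scores obey the spec invariants", {
  set.seed(43)
  genes <- sprintf("g%03d", 1:150)
  expr <- matrix(rnorm(150 * 3, 5), ncol = 3,
                 dimnames = list(genes, c("s1", "s2", "s3")))
  expr[, "s2"] <- expr[, "s1"]  # identical columns
  sets <- list(a = genes[1:15], b = genes[50:70])
  sc <- ssgsea_scores(expr, sets)
  expect_equal(sc[, "s1"], sc[, "s2"])

  # moving in-set genes to the top of one sample strictly raises its score
  expr2 <- expr
  expr2[sets$a, "s3"] <- max(expr2[, "s3"]) + seq_along(sets$a)
  sc2 <- ssgsea_scores(expr2, sets, normalize = FALSE)
  sc_raw <- ssgsea_scores(expr, sets, normalize = FALSE)
  expect_gt(sc2["a", "s3"], sc_raw["a", "s3"])

  # gene-order permutation invariance
  perm <- sample(nrow(expr))
  expect_equal(ssgsea_scores(expr[perm, ], sets), sc)

  # FPKM filter removes never-expressed genes before ranking
  fpkm <- matrix(5, nrow = 150, ncol = 3, dimnames = dimnames(expr))
  fpkm[genes[100:150], ] <- 0.2
  sc3 <- ssgsea_scores(expr, sets, fpkm = fpkm)
  expect_false(any(is.na(sc3)))

  # a set with no expressed gene is undefined, not zero
  sets4 <- c(sets, list(gone = genes[140:150]))
  sc4 <- ssgsea_scores(expr, sets4, fpkm = fpkm)
  expect_true(all(is.na(sc4["gone", ])))

  # random sets on permuted expression land mid-range, not at the extremes
  set.seed(44)
  reps <- vapply(1:100, function(i) {
    e <- matrix(sample(expr), nrow = nrow(expr), dimnames = dimnames(expr))
    ssgsea_scores(e, list(r = sample(genes, 20)), normalize = FALSE)[1, 1]
  }, numeric(1))
  null_scale <- mean(abs(range(reps)))
  expect_lt(abs(mean(reps)), null_scale / 2)
})

test_that("paired ssGSEA deltas are symmetric and rank shifted sets first", {
  genes <- sprintf("g%03d", 1:100)
  set.seed(45)
  expr <- matrix(rnorm(400, 5), ncol = 4,
                 dimnames = list(genes, c("p1A", "p1B", "p2A", "p2B")))
  expr[, "p1B"] <- expr[, "p1A"]
  sets <- list(a = genes[1:10], b = genes[11:30], c = genes[31:40])
  expr[sets$b, "p2B"] <- expr[sets$b, "p2B"] + 50
  sc <- ssgsea_scores(expr, sets)
  pairs <- data.frame(patient = c("p1", "p2"),
                      sample_a = c("p1A", "p2A"),
                      sample_b = c("p1B", "p2B"))
  d <- delta_ssgsea(sc, pairs)
  expect_true(all(d$delta[, "p1"] == 0))
  expect_equal(d$ranking$p2[1], "b")
  # swapping A and B leaves deltas unchanged
  pairs_sw <- data.frame(patient = pairs$patient,
                         sample_a = pairs$sample_b,
                         sample_b = pairs$sample_a)
  expect_equal(delta_ssgsea(sc, pairs_sw)$delta, d$delta)
  expect_error(delta_ssgsea(sc, data.frame(patient = "x",
                                           sample_a = "nope",
                                           sample_b = "p1B")), "absent")
})
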