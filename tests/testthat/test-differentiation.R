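test_that("undifferentiated and fully differentiated pairs hit the limits", {
  # identical allele frequencies, large n: all statistics near 0
  same <- dataset_from_counts(rbind(c(60, 40), c(60, 40)))
  af <- allele_frequencies(same)
  expect_lt(abs(gst(af)), 0.02)
  expect_lt(abs(jost_d(af)$overall), 0.05)
  # fixed for different alleles: complete differentiation
  fixed <- dataset_from_counts(rbind(c(40, 0), c(0, 40)))
  af2 <- allele_frequencies(fixed)
  expect_equal(gst(af2), 1, tolerance = 1e-12)
  expect_equal(hedrick_fst_prime(af2), 1, tolerance = 1e-12)
  expect_equal(jost_d(af2)$overall, 1, tolerance = 1e-12)
  # disjoint allele sets but polymorphic within: D = 1, F'ST = 1
  disj <- dataset_from_counts(rbind(c(10, 10, 0, 0), c(0, 0, 10, 10)))
  af3 <- allele_frequencies(disj)
  expect_equal(jost_d(af3)$overall, 1, tolerance = 1e-12)
  expect_equal(hedrick_fst_prime(af3), 1, tolerance = 1e-12)
})

test_that("estimators equal the brute-force formula oracle on toy counts", {
  cases <- list(rbind(c(6, 2), c(1, 7)),
                rbind(c(5, 3), c(5, 3)),
                rbind(c(7, 1), c(2, 2)),
                rbind(c(3, 3, 2), c(1, 6, 1)))
  for (cm in cases) {
    ds <- dataset_from_counts(cm)
    af <- allele_frequencies(ds)
    expect_equal(gst(af), oracle_gst(list(cm)), tolerance = 1e-12)
    expect_equal(hedrick_fst_prime(af), oracle_fst_prime(list(cm)),
                 tolerance = 1e-12)
    expect_equal(jost_d(af)$overall, oracle_jost_d(list(cm)),
                 tolerance = 1e-12)
  }
})

test_that("F'ST equals GST divided by its independently computed maximum", {
  cm <- rbind(c(12, 4, 4), c(2, 10, 8))
  af <- allele_frequencies(dataset_from_counts(cm))
  hh <- oracle_hs_ht(cm)
  gst_max <- (hh$k - 1) * (1 - hh$hs) / (hh$k - 1 + hh$hs)
  expect_equal(hedrick_fst_prime(af), gst(af) / gst_max, tolerance = 1e-12)
})

test_that("standardization inflates GST but never past 1", {
  fx <- get_fixture()
  af <- allele_frequencies(fx)
  pops <- af$pops
  set.seed(4)
  for (i in 1:10) {
    pair <- sample(pops, 2)
    g <- gst(af, pair)
    fp <- hedrick_fst_prime(af, pair)
    if (!is.na(g) && g > 0) expect_gt(fp, g)
    expect_lte(fp, 1 + 1e-9)
  }
})

test_that("statistics are invariant to allele relabeling and pop order", {
  ds <- random_dataset(seed = 21, n_pops = 3, n_per_pop = 10, n_loci = 3,
                       max_allele = 8, missing_rate = 0)
  af <- allele_frequencies(ds)
  relab <- ds; relab$calls[] <- relab$calls * 7L + 3L
  af_r <- allele_frequencies(relab)
  expect_equal(gst(af), gst(af_r), tolerance = 1e-12)
  expect_equal(jost_d(af)$overall, jost_d(af_r)$overall, tolerance = 1e-12)
  expect_equal(gst(af, c("pop3", "pop1")), gst(af, c("pop1", "pop3")),
               tolerance = 1e-12)
})

test_that("pairwise matrices reflect the population structure", {
  # three identical populations: all pairs near 0
  calls <- array(rep(c(1L, 2L), each = 9), c(9, 1, 2))
  ds <- genotype_dataset(calls, paste0("i", 1:9),
                         rep(c("a", "b", "c"), each = 3), "L1")
  pw <- pairwise_matrix(ds, "gst")
  expect_true(all(abs(pw$matrix[upper.tri(pw$matrix)]) < 0.2))
  # population c fixed for a different allele
  calls2 <- calls
  calls2[7:9, , ] <- 9L
  ds2 <- genotype_dataset(calls2, paste0("i", 1:9),
                          rep(c("a", "b", "c"), each = 3), "L1")
  pw2 <- pairwise_matrix(ds2, "fst_prime")
  expect_equal(unname(pw2$matrix["a", "c"]), 1, tolerance = 1e-9)
  expect_equal(unname(pw2$matrix["b", "c"]), 1, tolerance = 1e-9)
  expect_lt(pw2$matrix["a", "b"], 0.3) # near zero (bias can push it negative)
  expect_true(all(is.na(diag(pw2$matrix))))
  expect_equal(pw2$matrix, t(pw2$matrix))
})

test_that("permutation test attains its limits and guards resolution", {
  fixed <- dataset_from_counts(rbind(c(20, 0), c(0, 20)))
  pt <- permutation_test(fixed, c("p1", "p2"), "gst", n_perm = 99, seed = 2)
  expect_equal(pt$p_value, 1 / 100) # minimal attainable p
  mono <- dataset_from_counts(rbind(c(20, 0), c(20, 0)))
  expect_error(permutation_test(mono, c("p1", "p2"), n_perm = 50),
               "n_perm")
  # monomorphic data: statistic undefined for every permutation, p = 1
  ptm <- permutation_test(mono, c("p1", "p2"), "gst", n_perm = 99, seed = 2)
  expect_equal(ptm$p_value, 1)
})

test_that("permutation p-values are roughly uniform under panmixia", {
  # two samples from one pool: p should exceed 0.05 in most replicates
  set.seed(8)
  hits <- 0
  for (r in 1:15) {
    # two samples of HWE genotypes drawn from one shared allele pool
    n <- 40
    calls <- array(sample(1:4, n * 2, replace = TRUE), c(n, 1, 2))
    ds <- genotype_dataset(calls, sprintf("i%02d", 1:n),
                           rep(c("p1", "p2"), each = n / 2), "L1")
    pt <- permutation_test(ds, c("p1", "p2"), "gst", n_perm = 199,
                           seed = 100 + r)
    hits <- hits + (pt$p_value > 0.05)
  }
  expect_gte(hits, 12)
})

test_that("bonferroni flags match the direct comparison", {
  expect_equal(bonferroni(numeric(0)), logical(0))
  expect_false(any(bonferroni(rep(1, 10))))
  p <- c(0.001, 0.0017, 0.0018, 0.04, 0.6)
  n <- length(p)
  expect_equal(bonferroni(p, 0.05), p <= 0.05 / n)
  # 28 tests at alpha 0.05: threshold 0.0017857...
  p28 <- c(0.0017, rep(0.5, 27))
  expect_equal(bonferroni(p28, 0.05),
               c(TRUE, rep(FALSE, 27)))
})

test_that("bootstrap bounds behave at the edges and tighten with n", {
  fx <- get_fixture()
  small <- subset_individuals(fx, fx$populations %in% c("L1", "L2", "E1", "E2"))
  # single replicate with range bounds collapses onto that replicate
  b1 <- bootstrap_ci(small, n_boot = 1, seed = 5, bounds = "range")
  expect_equal(b1$lower[, -1], b1$upper[, -1])
  # width shrinks as per-population sample size grows
  width_at <- function(n_per_pop, seed) {
    ds <- generate_two_cluster_dataset(study_emulation_params(
      n_pops_group1 = 2, n_pops_group2 = 2, n_per_pop = c(n_per_pop,
                                                          n_per_pop),
      n_loci = 4, locus_alleles = rep(8L, 4), target_between = 0.2,
      seed = seed))
    b <- bootstrap_ci(ds, n_boot = 120, seed = 7)
    mean(as.matrix(b$upper[, -1] - b$lower[, -1]), na.rm = TRUE)
  }
  expect_lt(width_at(100, 31), width_at(10, 31))
})

test_that("bootstrap bounds of a monomorphic locus are exactly zero", {
  calls <- array(2L, c(12, 2, 2))
  set.seed(2)
  calls[, 2, ] <- sample(1:4, 24, replace = TRUE) # locus 2 polymorphic
  grp <- setNames(c("g1", "g1", "g2", "g2"), c("a", "b", "c", "d"))
  ds <- genotype_dataset(calls, paste0("i", 1:12),
                         rep(c("a", "b", "c", "d"), each = 3), c("L1", "L2"),
                         groups = grp)
  b <- bootstrap_ci(ds, n_boot = 100, seed = 3)
  expect_equal(unname(unlist(b$lower[1, -1])), c(0, 0, 0))
  expect_equal(unname(unlist(b$upper[1, -1])), c(0, 0, 0))
})

test_that("block summaries aggregate the three pair blocks correctly", {
  pops <- c("a", "b", "c", "d")
  m <- matrix(0.5, 4, 4, dimnames = list(pops, pops))
  diag(m) <- NA
  groups <- setNames(c("g1", "g1", "g2", "g2"), pops)
  bs <- block_summary(m, groups)
  expect_equal(bs$mean, rep(0.5, 3))
  expect_equal(bs$min, rep(0.5, 3))
  expect_equal(bs$max, rep(0.5, 3))
  expect_equal(bs$n_pairs, c(1, 1, 4))
  expect_error(block_summary(m, groups[1:3]), "unmapped")
})

test_that("per-locus group differentiation keys on the right populations", {
  fx <- get_fixture()
  ld <- locus_differentiation(fx)
  expect_equal(ld$locus, fx$loci)
  expect_equal(colnames(ld)[2:4],
               c("within_lignotuberous", "within_epicormic", "between"))
  # the injected locus dominates the between-group column
  expect_equal(which.max(ld$between), 1L)
})
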