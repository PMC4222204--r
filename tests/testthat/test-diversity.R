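# frequency table built directly from genotype counts per worked example
two_pop_counts <- function(c1, c2) {
  # one locus, allele counts per population (vectors over the same alleles)
  dataset_from_counts(rbind(c1, c2))
}

test_that("allele counts per locus match direct enumeration", {
  ds <- dataset_from_counts(rbind(c(8, 0, 0), c(3, 3, 2)))
  af <- allele_frequencies(ds)
  expect_equal(num_alleles(af, "p1"), 1) # monomorphic
  expect_equal(num_alleles(af, "p2"), 3)
  # brute-force count on a multi-locus synthetic population
  fx <- get_fixture()
  affx <- allele_frequencies(fx)
  p <- affx$pops[1]
  brute <- mean(vapply(seq_along(fx$loci), function(l) {
    a <- fx$calls[fx$populations == p, l, ]
    length(unique(a[!is.na(a)]))
  }, 0))
  expect_equal(num_alleles(affx, p), brute)
})

test_that("effective allele number follows 1 / sum(p^2)", {
  af <- allele_frequencies(dataset_from_counts(rbind(c(5, 5), c(9, 1))))
  expect_equal(effective_alleles(af, "p1"), 2)
  expect_equal(effective_alleles(af, "p2"), 1 / (0.81 + 0.01))
  af_mono <- allele_frequencies(dataset_from_counts(rbind(c(4, 0), c(2, 2))))
  expect_equal(effective_alleles(af_mono, "p1"), 1)
})

test_that("observed heterozygosity counts heterozygous genotypes", {
  # all homozygotes
  calls <- array(c(1L, 2L, 1L, 2L), c(2, 1, 2))
  ds <- genotype_dataset(calls, c("a", "b"), c("p", "p"), "L1")
  expect_equal(observed_heterozygosity(ds, "p"), 0)
  # all heterozygotes
  calls2 <- array(c(1L, 1L, 2L, 3L), c(2, 1, 2))
  ds2 <- genotype_dataset(calls2, c("a", "b"), c("p", "p"), "L1")
  expect_equal(observed_heterozygosity(ds2, "p"), 1)
  # mixed fixture population equals direct enumeration over loci
  fx <- get_fixture()
  p <- fx$populations[1]
  rows <- fx$populations == p
  brute <- mean(vapply(seq_along(fx$loci), function(l) {
    a1 <- fx$calls[rows, l, 1]; a2 <- fx$calls[rows, l, 2]
    ok <- !is.na(a1)
    mean(a1[ok] != a2[ok])
  }, 0))
  expect_equal(observed_heterozygosity(fx, p), brute)
})

test_that("unbiased expected heterozygosity uses the 2n/(2n-1) correction", {
  # p = (0.5, 0.5), n = 10 diploids
  af <- allele_frequencies(dataset_from_counts(rbind(c(10, 10), c(1, 1))))
  expect_equal(unbiased_expected_heterozygosity(af, "p1"), (20 / 19) * 0.5)
  # monomorphic locus
  af2 <- allele_frequencies(dataset_from_counts(rbind(c(20, 0), c(1, 1))))
  expect_equal(unbiased_expected_heterozygosity(af2, "p1"), 0)
  # large n converges to 1 - sum(p^2)
  af3 <- allele_frequencies(dataset_from_counts(rbind(c(3000, 1000),
                                                      c(1, 1))))
  expect_equal(unbiased_expected_heterozygosity(af3, "p1"), 0.375,
               tolerance = 1e-3)
})

test_that("Ae never exceeds A, with equality only for equifrequent alleles", {
  fx <- get_fixture()
  af <- allele_frequencies(fx)
  for (p in af$pops) {
    for (l in seq_along(af$loci)) {
      f <- af$freq[[l]][p, ]
      f <- f[f > 0]
      expect_lte(1 / sum(f^2), length(f) + 1e-12)
    }
    expect_lte(effective_alleles(af, p), num_alleles(af, p))
  }
  af_eq <- allele_frequencies(dataset_from_counts(rbind(c(4, 4, 4), c(2, 1, 1))))
  expect_equal(effective_alleles(af_eq, "p1"), num_alleles(af_eq, "p1"))
})

test_that("He is invariant under allele relabeling", {
  ds <- random_dataset(seed = 13, n_pops = 2, n_per_pop = 8, n_loci = 2,
                       max_allele = 6, missing_rate = 0)
  relab <- ds
  relab$calls[] <- relab$calls + 100L
  af1 <- allele_frequencies(ds); af2 <- allele_frequencies(relab)
  for (p in af1$pops)
    expect_equal(unbiased_expected_heterozygosity(af1, p),
                 unbiased_expected_heterozygosity(af2, p))
})

test_that("diversity table group rows equal the member-population means", {
  fx <- get_fixture()
  tab <- diversity_table(fx)
  per <- attr(tab, "per_population")
  for (g in unique(per$group)) {
    mrow <- tab[tab$population == paste(g, "mean"), ]
    expect_equal(mrow$A, mean(per$A[per$group == g]))
    expect_equal(mrow$He, mean(per$He[per$group == g]))
  }
  # standardization to a common n keeps the table well-formed
  tab25 <- diversity_table(fx, n_standardize = 25, seed = 3)
  per25 <- attr(tab25, "per_population")
  expect_true(all(per25$Ho >= 0 & per25$Ho <= 1))
  expect_true(all(per25$He >= 0 & per25$He <= 1))
  expect_true(all(per25$Ae <= per25$A + 1e-9))
})
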