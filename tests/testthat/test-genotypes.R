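genepop_lines <- c(
  "toy file",
  "locA",
  "POP",
  "a1 , 001002",
  "a2 , 001001",
  "POP",
  "b1 , 002002",
  "b2 , 000000")

test_that("a minimal GenePop file parses into the expected dataset", {
  f <- withr::local_tempfile(lines = genepop_lines, fileext = ".gen")
  ds <- read_genepop(f)
  expect_s3_class(ds, "genotype_dataset")
  expect_equal(length(ds$individuals), 4)
  expect_equal(unique(ds$populations), c("pop1", "pop2"))
  expect_equal(ds$loci, "locA")
  expect_equal(ds$calls[1, 1, ], c(1L, 2L))
  # the 000000 record is a missing call, excluded from n
  expect_true(all(is.na(ds$calls[4, 1, ])))
  af <- allele_frequencies(ds)
  expect_equal(unname(af$n[, 1]), c(2L, 1L))
  expect_equal(unname(af$freq[[1]]["pop1", ]), c(0.75, 0.25))
})

test_that("GenePop parse and structural errors name the offending line", {
  bad <- c("t", "locA", "locB", "POP", "x1 , 001002")
  f <- withr::local_tempfile(lines = bad, fileext = ".gen")
  expect_error(read_genepop(f), "expected 2 loci")
  bad2 <- c("t", "locA", "POP", "x1 001002")
  f2 <- withr::local_tempfile(lines = bad2, fileext = ".gen")
  expect_error(read_genepop(f2), "no ',' or tab")
})

test_that("write_genepop rejects empty loci and >3-digit alleles", {
  ds <- random_dataset(seed = 2, max_allele = 999)
  ds_big <- ds
  ds_big$calls[1, 1, 1] <- 1500L
  expect_error(write_genepop(ds_big, tempfile()), "encoding error")
  ds_empty <- ds
  ds_empty$loci <- character(0)
  expect_error(write_genepop(ds_empty, tempfile()), "empty locus")
})

test_that("GenePop round trip is the identity on the data model", {
  for (seed in 1:3) {
    ds <- random_dataset(seed = seed, n_pops = 4, n_per_pop = 5, n_loci = 3)
    f <- withr::local_tempfile(fileext = ".gen")
    write_genepop(ds, f)
    back <- read_genepop(f)
    expect_equal(unname(back$calls), unname(ds$calls))
    expect_equal(as.integer(factor(back$populations)),
                 as.integer(factor(ds$populations)))
    # a second write of the parsed copy is byte-identical (canonical form)
    f2 <- withr::local_tempfile(fileext = ".gen")
    write_genepop(back, f2)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("tabular genotype dialect round-trips including missing calls", {
  ds <- random_dataset(seed = 5, missing_rate = 0.2, max_allele = 400)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_tsv(ds, f)
  back <- read_genotypes_tsv(f)
  expect_equal(unname(back$calls), unname(ds$calls))
  expect_equal(back$populations, ds$populations)
  expect_equal(back$loci, ds$loci)
})

test_that("allele frequencies sum to 1 and respect missing data", {
  ds <- random_dataset(seed = 7, n_pops = 4, n_per_pop = 6, n_loci = 3,
                       max_allele = 5, missing_rate = 0.2)
  af <- allele_frequencies(ds)
  for (l in seq_along(af$loci))
    for (p in af$pops)
      if (af$n[p, l] > 0)
        expect_equal(sum(af$freq[[l]][p, ]), 1, tolerance = 1e-9)
  # an all-missing (pop, locus) has n = 0 and a zero frequency row
  ds$calls[ds$populations == "pop1", 2, ] <- NA_integer_
  af2 <- allele_frequencies(ds)
  expect_equal(unname(af2$n["pop1", 2]), 0L)
  expect_true(all(af2$freq[[2]]["pop1", ] == 0))
})

test_that("allele frequencies are invariant to individual order", {
  ds <- random_dataset(seed = 11, n_pops = 3, n_per_pop = 6, n_loci = 2,
                       max_allele = 6)
  set.seed(1)
  perm <- unlist(lapply(unique(ds$populations), function(p)
    sample(which(ds$populations == p))))
  af1 <- allele_frequencies(ds)
  af2 <- allele_frequencies(subset_individuals(ds, perm))
  expect_equal(af1$freq, af2$freq)
  expect_equal(af1$n, af2$n)
})

test_that("standardize_sample is deterministic, seed-sensitive and safe", {
  ds <- random_dataset(seed = 3, n_pops = 3, n_per_pop = 10, n_loci = 2)
  s1 <- standardize_sample(ds, 6, seed = 9)
  s2 <- standardize_sample(ds, 6, seed = 9)
  expect_identical(s1$individuals, s2$individuals)
  expect_true(all(table(s1$populations) == 6))
  s3 <- standardize_sample(ds, 6, seed = 10)
  expect_false(identical(s1$individuals, s3$individuals))
  expect_true(all(table(s3$populations) == 6))
  # n_per_pop equal to every population size: identity
  s4 <- standardize_sample(ds, 10, seed = 1)
  expect_identical(s4$individuals, ds$individuals)
  expect_error(standardize_sample(ds, 11), "smaller than n_per_pop")
})

test_that("half-missing calls are promoted to fully missing", {
  calls <- array(1L, c(2, 1, 2))
  calls[1, 1, 2] <- NA_integer_
  ds <- genotype_dataset(calls, c("a", "b"), c("p", "p"), "L1")
  expect_true(all(is.na(ds$calls[1, 1, ])))
  expect_false(anyNA(ds$calls[2, 1, ]))
})
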