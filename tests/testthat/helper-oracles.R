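# Independent brute-force implementations of the differentiation estimators,
# written directly from the published formulas and kept deliberately separate
# from the package's code paths. They take plain allele-count matrices
# (populations x alleles) so nothing is shared with the package's frequency
# containers.

# per-locus corrected heterozygosities from one count matrix
oracle_hs_ht <- function(counts) {
  k <- nrow(counts)
  n <- rowSums(counts) / 2              # diploid sample sizes
  p <- counts / rowSums(counts)
  nh <- k / sum(1 / n)                  # harmonic mean
  hs_raw <- mean(1 - rowSums(p^2))
  hs <- (2 * nh / (2 * nh - 1)) * hs_raw
  pbar <- colMeans(p)
  ht <- (1 - sum(pbar^2)) + hs / (2 * nh * k)
  list(hs = hs, ht = ht, k = k)
}

# multi-locus estimates from a list of count matrices (one per locus)
oracle_gst <- function(count_list) {
  hh <- lapply(count_list, oracle_hs_ht)
  num <- sum(vapply(hh, function(x) x$ht - x$hs, 0))
  den <- sum(vapply(hh, function(x) x$ht, 0))
  num / den
}

oracle_fst_prime <- function(count_list) {
  hh <- lapply(count_list, oracle_hs_ht)
  g <- oracle_gst(count_list)
  hs <- mean(vapply(hh, function(x) x$hs, 0))
  k <- hh[[1]]$k
  gst_max <- (k - 1) * (1 - hs) / (k - 1 + hs)
  g / gst_max
}

oracle_jost_d <- function(count_list) {
  d <- vapply(count_list, function(cm) {
    x <- oracle_hs_ht(cm)
    (x$k / (x$k - 1)) * (x$ht - x$hs) / (1 - x$hs)
  }, 0)
  mean(d)
}

# Build a genotype_dataset holding exactly the allele counts in `counts`
# (populations x alleles, one locus), using deterministic genotype order;
# allele copies are laid out so every count is realized exactly.
dataset_from_counts <- function(counts) {
  k <- nrow(counts)
  n <- rowSums(counts) / 2
  stopifnot(all(n == round(n)))
  calls <- NULL; popv <- character(0)
  for (j in seq_len(k)) {
    copies <- rep(seq_len(ncol(counts)), counts[j, ])
    m <- matrix(copies, ncol = 2)
    calls <- rbind(calls, m)
    popv <- c(popv, rep(paste0("p", j), n[j]))
  }
  arr <- array(NA_integer_, c(nrow(calls), 1, 2))
  arr[, 1, 1] <- calls[, 1]; arr[, 1, 2] <- calls[, 2]
  genotype_dataset(arr, sprintf("i%03d", seq_len(nrow(calls))), popv, "loc1")
}

# memoized study fixture shared across test files
fixture_env <- new.env()
get_fixture <- function() {
  if (is.null(fixture_env$ds)) fixture_env$ds <- study_fixture(seed = 42L)
  fixture_env$ds
}

# small random dataset for round-trip / property tests
random_dataset <- function(seed = 1, n_pops = 3, n_per_pop = 4, n_loci = 2,
                           max_allele = 999, missing_rate = 0.1) {
  set.seed(seed)
  n <- n_pops * n_per_pop
  calls <- array(sample(seq_len(max_allele), n * n_loci * 2, replace = TRUE),
                 c(n, n_loci, 2))
  miss <- array(runif(n * n_loci * 2) < missing_rate, c(n, n_loci, 2))
  calls[miss] <- NA_integer_
  genotype_dataset(calls, sprintf("ind%02d", 1:n),
                   rep(paste0("pop", seq_len(n_pops)), each = n_per_pop),
                   paste0("L", seq_len(n_loci)))
}
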