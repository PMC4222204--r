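# independent R evaluation of the summary-statistic definitions, for the
# oracle-equivalence test against the compiled implementation
r_summary_stats <- function(al, n1, n2) {
  L <- ncol(al)
  c1 <- 2 * n1
  pops <- list(seq_len(c1), (c1 + 1):(c1 + 2 * n2))
  per_pop <- function(rows) {
    sapply(seq_len(L), function(l) {
      x <- al[rows, l]
      p <- table(x) / length(x)
      c(A = length(p),
        He = (length(x) / (length(x) - 1)) * (1 - sum(p^2)),
        V = var(x),
        M = length(p) / (diff(range(x)) + 1))
    })
  }
  s1 <- per_pop(pops[[1]]); s2 <- per_pop(pops[[2]])
  nh <- 2 / (1 / n1 + 1 / n2)
  fst_num <- fst_den <- 0; dsum <- 0; dn <- 0; dmu2 <- 0
  for (l in seq_len(L)) {
    x1 <- al[pops[[1]], l]; x2 <- al[pops[[2]], l]
    p1 <- table(factor(x1, levels = sort(unique(al[, l])))) / length(x1)
    p2 <- table(factor(x2, levels = sort(unique(al[, l])))) / length(x2)
    hs <- (2 * nh / (2 * nh - 1)) * (1 - (sum(p1^2) + sum(p2^2)) / 2)
    ht <- (1 - sum(((p1 + p2) / 2)^2)) + hs / (4 * nh)
    if (ht > 0) { fst_num <- fst_num + ht - hs; fst_den <- fst_den + ht }
    if (ht > 0 && hs < 1) { dsum <- dsum + 2 * (ht - hs) / (1 - hs); dn <- dn + 1 }
    dmu2 <- dmu2 + (mean(x1) - mean(x2))^2 / L
  }
  psa <- 0
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    s <- 0
    for (l in seq_len(L)) {
      g1 <- sort(al[c(2 * i - 1, 2 * i), l])
      g2 <- sort(al[c(c1 + 2 * j - 1, c1 + 2 * j), l])
      sh <- if (all(g1 == g2)) 2 else if (any(g1 %in% g2)) 1 else 0
      s <- s + sh / 2
    }
    psa <- psa + s / L
  }
  unname(c(mean(s1["A", ]), mean(s1["He", ]), mean(s1["V", ]),
           mean(s1["M", ]),
           mean(s2["A", ]), mean(s2["He", ]), mean(s2["V", ]),
           mean(s2["M", ]),
           if (fst_den > 0) fst_num / fst_den else 0,
           if (dn > 0) dsum / dn else 0,
           1 - psa / (n1 * n2), dmu2))
}

test_that("the three scenarios are distinct and well-formed", {
  sc <- abc_scenarios()
  expect_length(sc, 3)
  expect_equal(vapply(sc, `[[`, 0L, "id"), 1:3)
  expect_equal(sc[[1]]$ancestral, "pop1")
  expect_equal(sc[[2]]$ancestral, "pop2")
  expect_equal(sc[[3]]$ancestral, "unsampled")
  expect_equal(sc[[3]]$bottlenecked, c("pop1", "pop2"))
})

test_that("prior draws respect their supports and the t1 > db truncation", {
  d <- sample_prior(5000, seed = 3)
  expect_true(all(d$Nb >= 10 & d$Nb <= 100))
  expect_true(all(d$N1 >= 1e4 & d$N1 <= 1e5))
  expect_true(all(d$db_years >= 250 & d$db_years <= 750))
  expect_true(all(d$t1_years > d$db_years))
  expect_true(all(d$db_gen %in% 1:3))
  expect_true(all(d$t1_gen >= 1))
  expect_true(all(d$mu >= 1e-4 & d$mu <= 1e-3))
  expect_true(all(d$gsm_p >= 0.1 & d$gsm_p <= 0.3))
  expect_true(all(d$sni >= 1e-8 & d$sni <= 1e-5))
  expect_identical(d, sample_prior(5000, seed = 3))
})

test_that("a zero mutation rate yields monomorphic loci", {
  draw <- data.frame(N1 = 2e4, N2 = 2e4, Nanc = 2e4, Nb = 50,
                     t1_years = 25000, db_years = 500, t1_gen = 100,
                     db_gen = 2, mu = 0, gsm_p = 0.2, sni = 0)
  ds <- simulate_dataset(1, draw, c(10L, 10L), n_loci = 5, seed = 2)
  expect_true(all(apply(ds$calls, 2, function(x) length(unique(c(x)))) == 1))
  s <- summary_stats(ds)
  expect_equal(unname(s["fst"]), 0)
  expect_equal(unname(s["He_pop1"]), 0)
  expect_equal(unname(s["gw_m_pop1"]), 1)
})

test_that("allele-size variance matches stepwise-mutation theory", {
  # nearly panmictic pair (shallow split, equal sizes): within-sample size
  # variance in repeat units approaches theta/2 = 2*N*mu
  N <- 5000; mu <- 2e-4
  draw <- data.frame(N1 = N, N2 = N, Nanc = N, Nb = N, t1_years = 125000,
                     db_years = 250, t1_gen = 30, db_gen = 1, mu = mu,
                     gsm_p = 0, sni = 0)
  ds <- simulate_dataset(1, draw, c(200L, 2L), n_loci = 1500, seed = 3)
  rows <- ds$populations == "pop1"
  vs <- vapply(seq_len(1500), function(l)
    var(c(ds$calls[rows, l, ])), 0)
  # allele sizes are in nucleotides (3 nt motif): variance scales by 9
  expect_equal(mean(vs) / 9, 2 * N * mu, tolerance = 0.15)
})

test_that("deep divergence drives differentiation toward its ceiling", {
  draw <- data.frame(N1 = 1e4, N2 = 1e4, Nanc = 1e4, Nb = 1e4,
                     t1_years = 2.5e7, db_years = 250, t1_gen = 1e5,
                     db_gen = 1, mu = 5e-4, gsm_p = 0.2, sni = 0)
  ds <- simulate_dataset(3, draw, c(20L, 20L), n_loci = 30, seed = 5)
  s <- summary_stats(ds)
  expect_gt(unname(s["jost_d"]), 0.5)
  expect_gt(unname(s["fst"]), 0.05)
})

test_that("compiled summary statistics equal an independent R evaluation", {
  for (seed in 1:3) {
    draw <- sample_prior(1, seed = 40 + seed)
    ds <- simulate_dataset(sample(1:3, 1), draw, c(8L, 6L), n_loci = 4,
                           seed = 50 + seed)
    al <- matrix(0L, 28, 4)
    al[seq(1, 28, 2), ] <- ds$calls[, , 1]
    al[seq(2, 28, 2), ] <- ds$calls[, , 2]
    expect_equal(unname(summary_stats(ds)), r_summary_stats(al, 8, 6),
                 tolerance = 1e-12)
  }
})

test_that("summary statistics have a stable schema and a sane null point", {
  nm <- summary_stat_names()
  expect_length(nm, 12)
  draw <- sample_prior(1, seed = 77)
  ds <- simulate_dataset(3, draw, c(12L, 12L), n_loci = 6, seed = 78)
  s <- summary_stats(ds)
  expect_named(s, nm)
  # duplicated population: pairwise differentiation collapses
  dup <- ds
  half <- which(dup$populations == "pop1")
  dup$calls[dup$populations == "pop2", , ] <- dup$calls[half, , ]
  s2 <- summary_stats(dup)
  expect_lt(abs(s2[["fst"]]), 0.03)
  expect_equal(s2[["dmu2"]], 0)
})

test_that("reference tables are reproducible and schema-stable", {
  t1 <- build_reference_table(2, sample_sizes = c(5L, 5L), n_loci = 3,
                              seed = 4)
  expect_equal(nrow(t1), 6)
  expect_equal(as.integer(table(t1$scenario)), rep(2L, 3))
  expect_true(all(summary_stat_names() %in% colnames(t1)))
  t2 <- build_reference_table(2, sample_sizes = c(5L, 5L), n_loci = 3,
                              seed = 4)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("rejection posteriors honor zero-distance and degenerate tables", {
  tab <- build_reference_table(40, sample_sizes = c(6L, 6L), n_loci = 3,
                               seed = 6)
  obs <- unlist(tab[17, summary_stat_names()])
  dp <- direct_posterior(obs, tab, n_closest = 1)
  expect_equal(unname(dp$prob[tab$scenario[17]]), 1)
  expect_equal(sum(dp$prob), 1)
  # single-scenario table: probability 1 regardless of obs
  one <- tab[tab$scenario == 2, ]
  dp1 <- direct_posterior(obs, one, n_closest = 10)
  expect_equal(unname(dp1$prob), c(0, 1, 0))
  # record order is irrelevant
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(direct_posterior(obs, perm, 15)$prob,
               direct_posterior(obs, tab, 15)$prob)
})

test_that("logistic posteriors are proper and fall back when degenerate", {
  tab <- build_reference_table(60, sample_sizes = c(6L, 6L), n_loci = 3,
                               seed = 8)
  obs <- colMeans(tab[, summary_stat_names()])
  lp <- logistic_posterior(obs, tab, n_closest = 150)
  expect_equal(sum(lp$prob), 1, tolerance = 1e-9)
  expect_true(all(lp$prob >= 0))
  one <- tab[tab$scenario == 1, ]
  expect_warning(lp1 <- logistic_posterior(obs, one, n_closest = 30),
                 "single-scenario")
  expect_equal(unname(lp1$prob), c(1, 0, 0))
})

test_that("posterior parameter quantiles are ordered and prior-like without data", {
  tab <- build_reference_table(400, sample_sizes = c(5L, 5L), n_loci = 2,
                               seed = 10)
  obs <- colMeans(tab[, summary_stat_names()])
  pp <- posterior_parameters(obs, tab, 2, n_closest = 100)
  expect_true(all(pp$q5 <= pp$q50 & pp$q50 <= pp$q95))
  # accepting every record with uniform weights recovers the prior
  all_pp <- posterior_parameters(obs, tab, 2, n_closest = 400,
                                 weighting = "uniform")
  sub <- tab[tab$scenario == 2, ]
  t1row <- all_pp[all_pp$parameter == "t1_years", ]
  expect_equal(t1row$q50, median(sub$t1_years), tolerance = 0.02)
  expect_equal(t1row$q5, quantile(sub$t1_years, 0.05, names = FALSE),
               tolerance = 0.05)
})

test_that("local-linear adjustment returns ordered, finite quantiles", {
  tab <- build_reference_table(300, sample_sizes = c(10L, 10L), n_loci = 6,
                               seed = 14)
  obs <- colMeans(tab[, summary_stat_names()])
  expect_no_warning(pp <- posterior_parameters(obs, tab, 1, n_closest = 150,
                                               adjust = "loclinear"))
  expect_true(all(is.finite(unlist(pp[, -1]))))
  expect_true(all(pp$q5 <= pp$q50 & pp$q50 <= pp$q95))
  # a rank-deficient design falls back to the unadjusted draws, warning
  degenerate <- tab
  degenerate$jost_d <- degenerate$fst # duplicated column: aliased design
  expect_warning(posterior_parameters(obs, degenerate, 1, n_closest = 150,
                                      adjust = "loclinear"),
                 "singular|unadjusted")
})

test_that("confidence evaluation is near chance for uninformative tables", {
  set.seed(5)
  fake <- data.frame(scenario = rep(1:3, each = 300),
                     matrix(rnorm(900 * 12), 900, 12))
  colnames(fake)[-1] <- summary_stat_names()
  ce <- confidence_evaluation(fake, n_pods = 40, n_closest = 100, seed = 2)
  expect_equal(unname(rowSums(ce$confusion)), rep(40, 3))
  expect_true(all(abs(ce$confidence - 1 / 3) < 0.2))
  expect_true(all(ce$type1 > 0.4 & ce$type1 < 0.9))
})
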