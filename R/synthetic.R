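# Synthetic genotype generator emulating the study design: two phenotype
# groups (6 + 8 populations), 25-35 diploids per population, 11 loci with a
# ~198-allele total budget, strong between-group but negligible within-group
# differentiation, and one locus carrying a near-fixed allele in one group
# only. Population frequencies follow a two-level Balding-Nichols-style
# Dirichlet drift model; the between-group drift parameter is calibrated by
# bisection so the realized between-group mean F'ST hits its target.

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  s <- sum(x)
  if (s <= 0) { # degenerate: all-zero draws from tiny shapes
    x <- as.numeric(alpha == max(alpha))
    s <- sum(x)
  }
  x / s
}

#' Parameters for the study-emulating generator
#'
#' Defaults encode the emulated study design: 6 + 8 populations in two
#' phenotype groups, 25-35 diploid individuals each, 11 loci with a total
#' allele budget of 198 (one 17-allele locus reserved for the selection-
#' outlier injection), a between-group standardized differentiation target of
#' 0.27 and near-zero within-group differentiation.
#'
#' @param n_pops_group1,n_pops_group2 populations per group.
#' @param group_names group labels (group 1 first).
#' @param n_per_pop inclusive range of diploid individuals per population.
#' @param n_loci number of loci.
#' @param locus_alleles allele-support size per locus (sums to the allele
#'   budget; the first locus is the 17-allele outlier slot).
#' @param target_between target between-group mean F'ST.
#' @param target_within admissible band for within-group F'ST.
#' @param within_drift Balding-Nichols drift of populations around their
#'   group frequencies.
#' @param anc_alpha symmetric Dirichlet concentration of ancestral allele
#'   frequencies (controls marker heterozygosity).
#' @param missing_rate fraction of calls set missing, uniformly at random.
#' @param seed integer seed; generation is deterministic given it.
#' @return a list of class \code{study_params}.
#' @export
study_emulation_params <- function(n_pops_group1 = 6L, n_pops_group2 = 8L,
                                   group_names = c("lignotuberous",
                                                   "epicormic"),
                                   n_per_pop = c(25L, 35L), n_loci = 11L,
                                   locus_alleles = c(17L, rep(18L, 9L), 19L),
                                   target_between = 0.27,
                                   target_within = c(-0.05, 0.05),
                                   within_drift = 0.005,
                                   anc_alpha = 0.3,
                                   missing_rate = 0,
                                   seed = 1L) {
  stopifnot(n_pops_group1 >= 2L, n_pops_group2 >= 2L,
            length(locus_alleles) == n_loci, all(locus_alleles >= 2L),
            target_between >= 0, target_between <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (target_between > 0 && target_between < max(abs(target_within)))
    stop("infeasible targets: nonzero between-group target inside the ",
         "within-group band cannot be calibrated")
  structure(list(n_pops_group1 = n_pops_group1, n_pops_group2 = n_pops_group2,
                 group_names = group_names, n_per_pop = n_per_pop,
                 n_loci = n_loci, locus_alleles = locus_alleles,
                 target_between = target_between,
                 target_within = target_within,
                 within_drift = within_drift, anc_alpha = anc_alpha,
                 missing_rate = missing_rate, seed = seed),
            class = "study_params")
}

default_locus_names <- function(n) {
  base <- c("C112", "D155", "A112", "B008", "B101", "C005", "D010", "A020",
            "B113", "C201", "D077")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("X%03d", seq_len(n - length(base))))
}

# Dirichlet draw through the quantile transform: with the uniforms fixed,
# the result is a continuous (and in drift, monotone-ish) function of the
# shape parameters — which keeps the calibration bisection well-behaved.
qdirichlet <- function(u, alpha) {
  x <- qgamma(u, shape = alpha)
  s <- sum(x)
  if (!is.finite(s) || s <= 0) {
    x <- as.numeric(alpha == max(alpha))
    s <- sum(x)
  }
  x / s
}

# one full realization at a given between-group drift; all randomness is
# pre-drawn from the seed so the realization is a deterministic continuous
# function of f_between
generate_realization <- function(params, f_between) {
  with_seed(params$seed, {
    g1 <- params$n_pops_group1; g2 <- params$n_pops_group2
    pops <- c(paste0("L", seq_len(g1)), paste0("E", seq_len(g2)))
    grp <- setNames(rep(params$group_names, c(g1, g2)), pops)
    size_range <- seq(params$n_per_pop[1], params$n_per_pop[2])
    sizes <- size_range[sample.int(length(size_range), g1 + g2,
                                   replace = TRUE)]
    n <- sum(sizes)
    calls <- array(NA_integer_, c(n, params$n_loci, 2))
    popv <- rep(pops, sizes)
    fw <- params$within_drift
    for (l in seq_len(params$n_loci)) {
      K <- params$locus_alleles[l]
      anc <- qdirichlet(runif(K), rep(params$anc_alpha, K))
      for (gi in 1:2) {
        u_g <- runif(K)
        gfreq <- if (f_between > 0)
          qdirichlet(u_g, anc * (1 - f_between) / f_between) else anc
        for (p in which(rep(1:2, c(g1, g2)) == gi)) {
          u_p <- runif(K)
          pfreq <- if (fw > 0)
            qdirichlet(u_p, gfreq * (1 - fw) / fw) else gfreq
          rows <- which(popv == pops[p])
          u_c <- runif(2L * length(rows))
          copies <- findInterval(u_c, cumsum(pfreq),
                                 rightmost.closed = TRUE) + 1L
          copies[copies > K] <- K
          calls[rows, l, 1] <- copies[seq_along(rows)]
          calls[rows, l, 2] <- copies[length(rows) + seq_along(rows)]
        }
      }
    }
    if (params$missing_rate > 0) {
      miss <- runif(n * params$n_loci) < params$missing_rate
      mm <- matrix(miss, n, params$n_loci)
      c1 <- calls[, , 1]; c2 <- calls[, , 2]
      c1[mm] <- NA_integer_; c2[mm] <- NA_integer_
      calls[, , 1] <- c1; calls[, , 2] <- c2
    }
    genotype_dataset(calls, sprintf("%s_i%02d", popv,
                                    unlist(lapply(sizes, seq_len))),
                     popv, default_locus_names(params$n_loci), groups = grp)
  })
}

realized_between <- function(ds) {
  pw <- pairwise_matrix(ds, "fst_prime")
  block_summary(pw, ds$groups)[3, "mean"]
}

#' Generate a calibrated two-cluster genotype dataset
#'
#' Draws ancestral allele frequencies per locus, drifts them into two group-
#' level frequency sets and then into population-level sets (Balding-Nichols
#' Dirichlet model at both levels), samples diploid genotypes under HWE, and
#' calibrates the between-group drift by bisection so the realized
#' between-group mean F'ST lands on the target (within +/- 0.03).
#'
#' @param params a [study_emulation_params()] object.
#' @param tol bisection stopping tolerance on the realized between-group
#'   mean F'ST.
#' @return a [genotype_dataset()] with group labels; attributes
#'   \code{"f_between"} (calibrated drift) and \code{"realized_between"}.
#' @export
generate_two_cluster_dataset <- function(params = study_emulation_params(),
                                         tol = 0.01) {
  target <- params$target_between
  if (target < 0.005) { # panmictic request: no between-group drift at all
    ds <- generate_realization(params, 0)
    attr(ds, "f_between") <- 0
    attr(ds, "realized_between") <- realized_between(ds)
    return(ds)
  }
  lo <- 1e-4; hi <- 0.5
  best <- NULL
  for (it in 1:18) {
    fb <- (lo + hi) / 2
    ds <- generate_realization(params, fb)
    got <- realized_between(ds)
    if (is.null(best) || abs(got - target) < abs(best$got - target))
      best <- list(ds = ds, fb = fb, got = got)
    if (abs(got - target) <= tol) break
    if (got > target) hi <- fb else lo <- fb
  }
  if (abs(best$got - target) > 0.03)
    stop(sprintf("calibration failed: realized %.3f vs target %.3f",
                 best$got, target))
  ds <- best$ds
  attr(ds, "f_between") <- best$fb
  attr(ds, "realized_between") <- best$got
  ds
}

#' Specification of a selection-outlier locus
#'
#' Describes a locus whose allele-frequency profile differs sharply between
#' the two phenotype groups while both groups share the same allele support:
#' one allele dominates in one group while no allele in the other group
#' exceeds a ceiling.
#'
#' @param n_alleles shared allele-support size.
#' @param dominant_allele allele state that dominates in
#'   \code{dominant_group}.
#' @param dominant_freq its frequency there.
#' @param dominant_group group label carrying the dominant allele.
#' @param max_other ceiling on allele frequencies in the other group.
#' @param locus name (or index) of the locus to replace.
#' @return list of class \code{outlier_spec}.
#' @export
outlier_locus_spec <- function(n_alleles = 17L, dominant_allele = 6L,
                               dominant_freq = 0.87,
                               dominant_group = "epicormic",
                               max_other = 0.2, locus = 1L) {
  stopifnot(n_alleles >= 2L, dominant_freq > 0, dominant_freq < 1,
            dominant_allele >= 1L, dominant_allele <= n_alleles)
  rest <- (1 - dominant_freq) / (n_alleles - 1L)
  f_dom <- rep(rest, n_alleles); f_dom[dominant_allele] <- dominant_freq
  # other group: smoothly decreasing frequencies, none above the ceiling
  w <- 0.93^seq_len(n_alleles)
  f_oth <- w / sum(w)
  if (max(f_oth) >= max_other)
    stop("cannot satisfy ceiling ", max_other, " with ", n_alleles, " alleles")
  if (abs(sum(f_dom) - 1) > 1e-9 || abs(sum(f_oth) - 1) > 1e-9)
    stop("frequencies must sum to 1")
  structure(list(n_alleles = n_alleles, dominant_allele = dominant_allele,
                 dominant_freq = dominant_freq,
                 dominant_group = dominant_group, max_other = max_other,
                 locus = locus, freq_dominant = f_dom, freq_other = f_oth),
            class = "outlier_spec")
}

#' Inject a selection-outlier locus into a dataset
#'
#' Replaces one locus with genotypes drawn from group-specific frequency
#' vectors per [outlier_locus_spec()]; populations drift slightly around
#' their group vector so within-group differentiation at the locus stays
#' small. Missing-call positions at the locus are preserved.
#'
#' @param ds a [genotype_dataset()] with group labels.
#' @param spec an [outlier_locus_spec()].
#' @param within_drift population-level Balding-Nichols drift.
#' @param seed integer seed.
#' @return the modified [genotype_dataset()].
#' @export
inject_outlier_locus <- function(ds, spec = outlier_locus_spec(),
                                 within_drift = 0.005, seed = 1L) {
  if (is.null(ds$groups)) stop("dataset has no group labels")
  l <- if (is.character(spec$locus)) match(spec$locus, ds$loci) else spec$locus
  if (is.na(l) || l < 1L || l > length(ds$loci)) stop("no such locus")
  with_seed(seed, {
    for (p in pop_levels(ds)) {
      base <- if (ds$groups[p] == spec$dominant_group) spec$freq_dominant
              else spec$freq_other
      pfreq <- if (within_drift > 0)
        rdirichlet1(base * (1 - within_drift) / within_drift) else base
      rows <- which(ds$populations == p)
      miss <- is.na(ds$calls[rows, l, 1])
      copies <- sample.int(spec$n_alleles, 2L * length(rows), replace = TRUE,
                           prob = pfreq)
      ds$calls[rows, l, 1] <- ifelse(miss, NA_integer_,
                                     copies[seq_along(rows)])
      ds$calls[rows, l, 2] <- ifelse(miss, NA_integer_,
                                     copies[length(rows) + seq_along(rows)])
    }
  })
  ds
}

#' Study-emulating fixture: calibrated two-cluster data plus outlier locus
#'
#' Convenience wrapper producing the canonical synthetic dataset used
#' throughout the package's tests and examples: a calibrated two-group
#' dataset with the selection-outlier locus injected at its first locus.
#'
#' @param seed integer seed.
#' @param params a [study_emulation_params()] (its seed is overridden).
#' @param spec an [outlier_locus_spec()].
#' @return a [genotype_dataset()] with group labels.
#' @export
study_fixture <- function(seed = 42L, params = study_emulation_params(),
                          spec = outlier_locus_spec()) {
  params$seed <- seed
  ds <- generate_two_cluster_dataset(params)
  inject_outlier_locus(ds, spec, within_drift = params$within_drift,
                       seed = seed + 1L)
}
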