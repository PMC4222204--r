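# Per-population diversity statistics: mean alleles per locus (A), effective
# alleles (Ae), observed heterozygosity (Ho), unbiased expected
# heterozygosity (He, Nei 1978 small-sample correction). All statistics
# average over *defined* loci only: a (population, locus) with n = 0 is
# undefined and simply drops out of the mean.

defined_loci <- function(freqs, pop, min_n = 1L) {
  which(freqs$n[pop, ] >= min_n)
}

#' Mean number of alleles per locus
#' @param freqs an [allele_frequencies()] table.
#' @param pop population id.
#' @return mean over defined loci of the number of alleles with frequency > 0;
#'   \code{NA} if no locus is defined.
#' @export
num_alleles <- function(freqs, pop) {
  li <- defined_loci(freqs, pop)
  if (!length(li)) return(NA_real_)
  mean(vapply(li, function(l) sum(freqs$freq[[l]][pop, ] > 0), 0))
}

#' Mean effective number of alleles per locus
#'
#' Per locus \code{Ae = 1 / sum(p_i^2)}; averaged over defined loci.
#' @inheritParams num_alleles
#' @export
effective_alleles <- function(freqs, pop) {
  li <- defined_loci(freqs, pop)
  if (!length(li)) return(NA_real_)
  mean(vapply(li, function(l) 1 / sum(freqs$freq[[l]][pop, ]^2), 0))
}

#' Observed heterozygosity
#'
#' Fraction of non-missing genotypes whose two alleles differ, averaged over
#' loci with at least one genotype.
#' @param ds a [genotype_dataset()].
#' @param pop population id.
#' @export
observed_heterozygosity <- function(ds, pop) {
  rows <- which(ds$populations == pop)
  if (!length(rows)) stop("unknown population: ", pop)
  ho <- vapply(seq_along(ds$loci), function(l) {
    a1 <- ds$calls[rows, l, 1]; a2 <- ds$calls[rows, l, 2]
    ok <- !is.na(a1)
    if (!any(ok)) return(NA_real_)
    mean(a1[ok] != a2[ok])
  }, 0)
  if (all(is.na(ho))) NA_real_ else mean(ho, na.rm = TRUE)
}

#' Unbiased expected heterozygosity
#'
#' Per locus \code{He = (2n/(2n-1)) * (1 - sum(p_i^2))} (Nei's small-sample
#' correction); averaged over loci with \code{n >= 2}.
#' @inheritParams num_alleles
#' @export
unbiased_expected_heterozygosity <- function(freqs, pop) {
  li <- defined_loci(freqs, pop, min_n = 2L)
  if (!length(li)) return(NA_real_)
  mean(vapply(li, function(l) {
    n <- freqs$n[pop, l]
    (2 * n / (2 * n - 1)) * (1 - sum(freqs$freq[[l]][pop, ]^2))
  }, 0))
}

#' Per-population diversity table with group summaries
#'
#' Computes A, Ae, Ho and He for every population, optionally after
#' standardizing all populations to a common sample size, and appends
#' per-group mean and standard deviation rows when group labels are present.
#'
#' @param ds a [genotype_dataset()].
#' @param n_standardize optional common sample size (e.g. 25); when given,
#'   [standardize_sample()] is applied first.
#' @param seed seed for the standardizing subsample.
#' @return a \code{data.frame} with columns \code{population}, \code{group},
#'   \code{A}, \code{Ae}, \code{Ho}, \code{He}; group summary rows are named
#'   \code{"<group> mean"} / \code{"<group> sd"}. The per-population block
#'   carries attribute \code{"per_population"}.
#' @export
diversity_table <- function(ds, n_standardize = NULL, seed = 1L) {
  if (!is.null(n_standardize))
    ds <- standardize_sample(ds, n_standardize, seed = seed)
  freqs <- allele_frequencies(ds)
  pops <- freqs$pops
  tab <- data.frame(
    population = pops,
    group = if (is.null(ds$groups)) NA_character_ else ds$groups[pops],
    A  = vapply(pops, function(p) num_alleles(freqs, p), 0),
    Ae = vapply(pops, function(p) effective_alleles(freqs, p), 0),
    Ho = vapply(pops, function(p) observed_heterozygosity(ds, p), 0),
    He = vapply(pops, function(p) unbiased_expected_heterozygosity(freqs, p), 0),
    row.names = NULL)
  out <- tab
  if (!is.null(ds$groups)) {
    for (g in unique(tab$group)) {
      sub <- tab[tab$group == g, c("A", "Ae", "Ho", "He")]
      out <- rbind(out,
        data.frame(population = paste(g, "mean"), group = g,
                   as.list(colMeans(sub)), row.names = NULL),
        data.frame(population = paste(g, "sd"), group = g,
                   as.list(vapply(sub, sd, 0)), row.names = NULL))
    }
  }
  attr(out, "per_population") <- tab
  out
}

#' Group means of a printed diversity table
#'
#' Utility for published per-population diversity tables: computes the
#' arithmetic mean and sd of each numeric column within each group, for
#' comparison with the table's own printed summary rows.
#'
#' @param tab data.frame with columns \code{population}, \code{group} and
#'   numeric statistic columns.
#' @return data.frame with one mean row and one sd row per group.
#' @export
diversity_group_means <- function(tab) {
  num <- vapply(tab, is.numeric, TRUE)
  do.call(rbind, lapply(split(tab, tab$group), function(sub) {
    data.frame(group = sub$group[1],
               stat = c("mean", "sd"),
               rbind(colMeans(sub[num]), vapply(sub[num], sd, 0)),
               row.names = NULL)
  }))
}
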