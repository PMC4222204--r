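# Differentiation statistics over population allele-frequency tables.
#
# Estimator: Nei & Chesser (1983) bias-corrected heterozygosities in the
# frequency-only (HWE-expected) form,
#   Hs_hat = (2*nh / (2*nh - 1)) * (1 - mean_i sum_a p_ia^2)
#   Ht_hat = (1 - sum_a pbar_a^2) + Hs_hat / (2 * nh * k)
# with nh the harmonic mean of the per-population diploid sample sizes and
# pbar the unweighted mean frequency vector. GST = (Ht - Hs)/Ht summed over
# loci; Hedrick's standardized G'ST and Jost's D derive from the same
# per-locus (Hs, Ht) pairs. Negative estimates are reported as computed.

# per-locus corrected (Hs, Ht, k) for a set of populations; NA rows where
# fewer than 2 populations have data.
locus_hs_ht <- function(freqs, pops) {
  L <- length(freqs$loci)
  out <- matrix(NA_real_, L, 3, dimnames = list(freqs$loci, c("Hs", "Ht", "k")))
  for (l in seq_len(L)) {
    n <- freqs$n[pops, l]
    use <- n > 0
    if (sum(use) < 2) next
    p <- freqs$freq[[l]][pops[use], , drop = FALSE]
    n <- n[use]
    k <- nrow(p)
    nh <- k / sum(1 / n)
    hs_raw <- 1 - mean(rowSums(p^2))
    hs <- (2 * nh / (2 * nh - 1)) * hs_raw
    pbar <- colMeans(p)
    ht <- (1 - sum(pbar^2)) + hs / (2 * nh * k)
    out[l, ] <- c(hs, ht, k)
  }
  out
}

#' Multi-locus GST (bias-corrected FST estimate)
#'
#' Nei-Chesser bias-corrected GST over a set of populations, aggregated over
#' loci by summing numerators and denominators:
#' \code{sum(Ht - Hs) / sum(Ht)}. May be slightly negative for undifferentiated
#' samples (reported as computed, never clamped).
#'
#' @param freqs an [allele_frequencies()] table.
#' @param pops character vector of populations (default: all in \code{freqs}).
#' @param per_locus if \code{TRUE}, also return the per-locus values.
#' @return the multi-locus estimate (\code{NA} if every locus is monomorphic
#'   or undefined); with \code{per_locus = TRUE}, a list with elements
#'   \code{overall} and \code{per_locus}.
#' @export
gst <- function(freqs, pops = freqs$pops, per_locus = FALSE) {
  hh <- locus_hs_ht(freqs, pops)
  ok <- !is.na(hh[, "Ht"]) & hh[, "Ht"] > 0
  overall <- if (!any(ok)) NA_real_ else
    sum(hh[ok, "Ht"] - hh[ok, "Hs"]) / sum(hh[ok, "Ht"])
  if (!per_locus) return(overall)
  pl <- ifelse(ok, (hh[, "Ht"] - hh[, "Hs"]) / hh[, "Ht"], NA_real_)
  list(overall = overall, per_locus = setNames(pl, freqs$loci))
}

#' Hedrick's standardized F'ST
#'
#' Standardizes GST by its maximum attainable value given within-population
#' heterozygosity, via the closed form
#' \deqn{G'_{ST} = G_{ST} (k - 1 + H_S) / ((k - 1)(1 - H_S))}
#' which equals \code{GST / GST_max} with
#' \code{GST_max = (k-1)(1-Hs) / (k-1+Hs)}. \code{Hs} is the mean per-locus
#' corrected within-population heterozygosity.
#'
#' @inheritParams gst
#' @return the standardized estimate; \code{NA} (flagged undefined) when
#'   \code{Hs = 1}.
#' @export
hedrick_fst_prime <- function(freqs, pops = freqs$pops) {
  hh <- locus_hs_ht(freqs, pops)
  ok <- !is.na(hh[, "Ht"]) & hh[, "Ht"] > 0
  if (!any(ok)) return(NA_real_)
  g <- sum(hh[ok, "Ht"] - hh[ok, "Hs"]) / sum(hh[ok, "Ht"])
  hs <- mean(hh[ok, "Hs"])
  k <- max(hh[ok, "k"])
  if (hs >= 1) return(NA_real_)
  g * (k - 1 + hs) / ((k - 1) * (1 - hs))
}

#' Jost's D
#'
#' Per locus \deqn{D = (k/(k-1)) (H_T - H_S) / (1 - H_S)} with bias-corrected
#' heterozygosities; the multi-locus summary is the arithmetic mean over
#' defined loci (harmonic-mean variant available).
#'
#' @inheritParams gst
#' @param aggregate \code{"arithmetic"} (default) or \code{"harmonic"}
#'   multi-locus mean.
#' @return list with \code{overall} and per-locus vector \code{per_locus}.
#' @export
jost_d <- function(freqs, pops = freqs$pops,
                   aggregate = c("arithmetic", "harmonic")) {
  aggregate <- match.arg(aggregate)
  hh <- locus_hs_ht(freqs, pops)
  ok <- !is.na(hh[, "Hs"]) & hh[, "Hs"] < 1
  d <- rep(NA_real_, nrow(hh))
  d[ok] <- (hh[ok, "k"] / (hh[ok, "k"] - 1)) *
    (hh[ok, "Ht"] - hh[ok, "Hs"]) / (1 - hh[ok, "Hs"])
  overall <- if (!any(ok)) NA_real_
  else if (aggregate == "arithmetic") mean(d[ok])
  else 1 / mean(1 / pmax(d[ok], 1e-12))
  list(overall = overall, per_locus = setNames(d, freqs$loci))
}

stat_fun <- function(statistic) {
  switch(statistic,
         gst = function(freqs, pops) gst(freqs, pops),
         fst_prime = hedrick_fst_prime,
         jost_d = function(freqs, pops) jost_d(freqs, pops)$overall,
         stop("unknown statistic: ", statistic))
}

#' Pairwise differentiation matrix
#'
#' Evaluates a differentiation statistic on every unordered pair of
#' populations (so \code{k = 2} in any standardization).
#'
#' @param ds a [genotype_dataset()].
#' @param statistic one of \code{"fst_prime"}, \code{"gst"}, \code{"jost_d"}.
#' @param n_standardize optional common per-population sample size applied via
#'   [standardize_sample()] before computing.
#' @param seed seed for the standardizing subsample.
#' @return object of class \code{pairwise_diff}: list with \code{statistic},
#'   symmetric \code{matrix} (diagonal \code{NA}), and \code{pops}.
#' @export
pairwise_matrix <- function(ds, statistic = "fst_prime",
                            n_standardize = NULL, seed = 1L) {
  if (!is.null(n_standardize))
    ds <- standardize_sample(ds, n_standardize, seed = seed)
  freqs <- allele_frequencies(ds)
  pops <- freqs$pops
  if (length(pops) < 2) stop("need at least 2 populations")
  f <- stat_fun(statistic)
  m <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)])
    for (j in (i + 1):length(pops))
      m[i, j] <- m[j, i] <- f(freqs, pops[c(i, j)])
  structure(list(statistic = statistic, matrix = m, pops = pops),
            class = "pairwise_diff")
}

#' @export
print.pairwise_diff <- function(x, ...) {
  cat("pairwise_diff:", x$statistic, "over", length(x$pops), "populations\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Permutation test for pairwise differentiation
#'
#' Permutes individuals between the two populations and recomputes the
#' statistic; \code{p = (1 + #\{perm >= observed\}) / (1 + n_perm)}.
#'
#' @param ds a [genotype_dataset()].
#' @param pair character vector of two population ids.
#' @param statistic as in [pairwise_matrix()].
#' @param n_perm number of permutations (at least 99).
#' @param seed integer seed.
#' @return list with \code{observed}, \code{p_value}, \code{n_perm}.
#' @export
permutation_test <- function(ds, pair, statistic = "fst_prime",
                             n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be >= 99 for usable resolution")
  if (length(pair) != 2L) stop("`pair` must name exactly 2 populations")
  rows <- which(ds$populations %in% pair)
  sub <- subset_individuals(ds, rows)
  f <- stat_fun(statistic)
  obs <- f(allele_frequencies(sub), pair)
  if (is.na(obs)) # statistic undefined (e.g. monomorphic): nothing to test
    return(list(observed = obs, p_value = 1, n_perm = n_perm))
  labs <- sub$populations
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    sub$populations <- sample(labs)
    f(allele_frequencies(sub), pair)
  }, 0))
  # a permuted statistic can be NA if one shuffled sample is empty at a locus
  p <- (1 + sum(perm >= obs, na.rm = TRUE)) / (1 + n_perm)
  list(observed = obs, p_value = p, n_perm = n_perm)
}

#' Bonferroni significance flags
#' @param pvals numeric vector of p-values.
#' @param alpha family-wise error rate.
#' @return logical vector: \code{p <= alpha / length(pvals)}.
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (!length(pvals)) return(logical(0))
  pvals <= alpha / length(pvals)
}

#' Per-locus differentiation within and between phenotype groups
#'
#' Computes a per-locus statistic (default Jost's D) three ways: across the
#' populations of group 1, across the populations of group 2, and between the
#' two groups treated as two pooled units (\code{k = 2}).
#'
#' @param ds a [genotype_dataset()] with group labels (or supply
#'   \code{groups}).
#' @param groups named character vector population -> group; defaults to
#'   \code{ds$groups}.
#' @param statistic \code{"jost_d"} or \code{"gst"}.
#' @return data.frame: locus, then one column per grouping
#'   (\code{within_<g1>}, \code{within_<g2>}, \code{between}).
#' @export
locus_differentiation <- function(ds, groups = ds$groups,
                                  statistic = "jost_d") {
  gs <- grouping_sets(ds, groups)
  per_locus <- function(dsx, pops) {
    freqs <- allele_frequencies(dsx, subset = pops)
    if (statistic == "jost_d") jost_d(freqs, pops)$per_locus
    else gst(freqs, pops, per_locus = TRUE)$per_locus
  }
  pooled <- pool_groups(ds, groups)
  out <- data.frame(locus = ds$loci,
                    w1 = per_locus(ds, gs$pops1),
                    w2 = per_locus(ds, gs$pops2),
                    between = per_locus(pooled, unique(pooled$populations)),
                    row.names = NULL)
  colnames(out)[2:3] <- paste0("within_", c(gs$g1, gs$g2))
  out
}

grouping_sets <- function(ds, groups) {
  if (is.null(groups)) stop("group labels required")
  gl <- unique(groups[pop_levels(ds)])
  if (length(gl) != 2L) stop("exactly 2 groups required, found ", length(gl))
  list(g1 = gl[1], g2 = gl[2],
       pops1 = pop_levels(ds)[groups[pop_levels(ds)] == gl[1]],
       pops2 = pop_levels(ds)[groups[pop_levels(ds)] == gl[2]])
}

# relabel populations by their group so each group is one pooled population
pool_groups <- function(ds, groups) {
  ds2 <- ds
  ds2$populations <- unname(groups[ds$populations])
  ds2$groups <- setNames(unique(ds2$populations), unique(ds2$populations))
  ds2
}

#' Bootstrap bounds for per-locus differentiation
#'
#' Resamples individuals with replacement within populations and recomputes
#' [locus_differentiation()]; returns per-locus lower/upper bounds for each
#' grouping, as percentile bounds (default 2.5/97.5%) or the replicate range.
#'
#' @inheritParams locus_differentiation
#' @param n_boot number of bootstrap replicates (at least 100).
#' @param seed integer seed.
#' @param bounds \code{"percentile"} or \code{"range"}.
#' @param probs percentile bounds when \code{bounds = "percentile"}.
#' @return list with \code{point} (the unresampled table) and \code{lower} /
#'   \code{upper} data.frames of the same shape.
#' @export
bootstrap_ci <- function(ds, groups = ds$groups, statistic = "jost_d",
                         n_boot = 1000L, seed = 1L,
                         bounds = c("percentile", "range"),
                         probs = c(0.025, 0.975)) {
  bounds <- match.arg(bounds)
  if (n_boot < 1L) stop("n_boot must be positive")
  if (n_boot < 100L && bounds == "percentile")
    warning("n_boot < 100 gives coarse percentile bounds")
  sizes <- table(ds$populations)
  if (any(sizes == 1L)) {
    warning("excluding size-1 population(s): ",
            paste(names(sizes)[sizes == 1L], collapse = ", "))
    ds <- subset_individuals(ds, ds$populations %in% names(sizes)[sizes > 1L])
  }
  point <- locus_differentiation(ds, groups, statistic)
  byp <- split(seq_along(ds$populations), ds$populations)
  reps <- with_seed(seed, lapply(seq_len(n_boot), function(b) {
    idx <- unlist(lapply(byp, function(r) sample(r, length(r), replace = TRUE)))
    as.matrix(locus_differentiation(subset_individuals(ds, idx),
                                    groups, statistic)[, -1])
  }))
  arr <- simplify2array(reps)  # loci x groupings x reps
  qs <- if (bounds == "percentile") {
    list(lo = apply(arr, c(1, 2), quantile, probs[1], na.rm = TRUE),
         hi = apply(arr, c(1, 2), quantile, probs[2], na.rm = TRUE))
  } else {
    list(lo = apply(arr, c(1, 2), min, na.rm = TRUE),
         hi = apply(arr, c(1, 2), max, na.rm = TRUE))
  }
  shape <- function(m) data.frame(locus = point$locus, m, row.names = NULL,
                                  check.names = FALSE)
  list(point = point, lower = shape(qs$lo), upper = shape(qs$hi),
       n_boot = n_boot, bounds = bounds, seed = seed)
}

#' Block summary of a pairwise matrix over two phenotype groups
#'
#' Mean, min and max of the pairwise values within group 1, within group 2,
#' and between the groups.
#'
#' @param pw a [pairwise_matrix()] result, or a plain symmetric matrix with
#'   population dimnames.
#' @param groups named character vector population -> group (exactly 2 groups).
#' @return data.frame with rows \code{within_<g1>}, \code{within_<g2>},
#'   \code{between} and columns \code{mean}, \code{min}, \code{max},
#'   \code{n_pairs}. A group with < 2 populations yields an \code{NA} row.
#' @export
block_summary <- function(pw, groups) {
  m <- if (inherits(pw, "pairwise_diff")) pw$matrix else pw
  pops <- rownames(m)
  bad <- setdiff(pops, names(groups))
  if (length(bad)) stop("unmapped population(s): ", paste(bad, collapse = ", "))
  g <- groups[pops]
  gl <- unique(g)
  if (length(gl) != 2L) stop("exactly 2 groups required")
  vals <- function(sel1, sel2, cross) {
    x <- m[sel1, sel2, drop = FALSE]
    if (!cross) x <- x[upper.tri(x)]
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA, NA, NA, 0))
    c(mean(x), min(x), max(x), length(x))
  }
  out <- rbind(vals(g == gl[1], g == gl[1], FALSE),
               vals(g == gl[2], g == gl[2], FALSE),
               vals(g == gl[1], g == gl[2], TRUE))
  out <- data.frame(block = c(paste0("within_", gl), "between"), out,
                    row.names = NULL)
  colnames(out)[2:5] <- c("mean", "min", "max", "n_pairs")
  out
}

#' Read a lower-triangular pairwise matrix from TSV
#'
#' The layout used for published pairwise-differentiation tables: a header
#' row naming all but the last population, then one row per population from
#' the second onward with its values against earlier populations.
#'
#' @param path file path.
#' @return symmetric numeric matrix with \code{NA} diagonal.
#' @export
read_pairwise_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(lines[1], "\t")[[1]]
  hdr <- hdr[nzchar(hdr)]
  rows <- strsplit(lines[-1], "\t")
  rn <- vapply(rows, `[`, "", 1)
  pops <- unique(c(hdr, rn))
  m <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  for (r in rows) {
    i <- match(r[1], pops)
    v <- as.numeric(r[-1])
    m[i, seq_along(v)] <- v
    m[seq_along(v), i] <- v
  }
  m
}
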