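# FDIST-style FST-outlier detection: simulate a neutral island-model null
# cloud of per-locus (He, FST) values at the observed multi-locus FST, build
# median and 99% quantile envelope curves over heterozygosity, and classify
# observed loci against the envelope.

#' Observed per-locus heterozygosity and FST
#'
#' Per-locus corrected within-population heterozygosity (the He axis of an
#' outlier scan) and per-locus GST, over a chosen population set.
#'
#' @param ds a [genotype_dataset()].
#' @param pops populations to include (default all).
#' @return data.frame with columns \code{locus}, \code{He}, \code{Fst}.
#' @export
observed_locus_stats <- function(ds, pops = NULL) {
  freqs <- allele_frequencies(ds, subset = pops)
  hh <- locus_hs_ht(freqs, freqs$pops)
  fst <- ifelse(!is.na(hh[, "Ht"]) & hh[, "Ht"] > 0,
                (hh[, "Ht"] - hh[, "Hs"]) / hh[, "Ht"], NA_real_)
  data.frame(locus = freqs$loci, He = unname(hh[, "Hs"]), Fst = unname(fst),
             row.names = NULL)
}

#' Simulate the neutral (He, FST) cloud
#'
#' Coalescent simulation of unlinked loci in a finite symmetric island model
#' whose migration rate is set so the expected FST matches \code{target_fst}
#' (the infinite-island relation \code{FST = 1/(1 + 4Nm)} with the
#' finite-deme correction \code{((d-1)/d)^2}). Per-locus heterozygosity is
#' varied by drawing the scaled mutation rate log-uniformly, so the cloud
#' spans the He axis. Sample He and FST use the same Nei-Chesser estimators
#' as the rest of the package. \code{target_fst} below 0.001 simulates
#' panmixia.
#'
#' @param target_fst expected neutral FST in [0, 1).
#' @param sample_sizes diploid sample size per sampled population.
#' @param n_demes islands in the model (sampled populations occupy the first
#'   \code{length(sample_sizes)} of them).
#' @param n_loci cloud size.
#' @param mutation list: \code{model} ("smm", "iam" or "gsm"),
#'   \code{theta_range} (log-uniform support of the metapopulation-scale
#'   4*N*d*mu), \code{gsm_p} (geometric parameter, GSM only).
#' @param calibrate re-tune the migration rate on a pilot cloud so the
#'   realized mean FST matches \code{target_fst} (mutation otherwise biases
#'   the analytic inversion slightly downward).
#' @param pilot_loci pilot cloud size for the calibration step.
#' @param seed integer seed.
#' @return data.frame of class \code{neutral_cloud} with columns \code{He},
#'   \code{Fst} (monomorphic loci dropped); simulation settings are attached
#'   as attribute \code{"settings"}.
#' @export
simulate_neutral_cloud <- function(target_fst, sample_sizes, n_demes = 100L,
                                   n_loci = 20000L,
                                   mutation = list(model = "smm",
                                                   theta_range = c(0.2, 30),
                                                   gsm_p = 0.22),
                                   calibrate = TRUE, pilot_loci = 1000L,
                                   seed = 1L) {
  stopifnot(target_fst >= 0, target_fst < 1, n_loci >= 1)
  model <- match(match.arg(mutation$model, c("smm", "iam", "gsm")),
                 c("smm", "iam", "gsm")) - 1L
  mig <- if (target_fst < 1e-3) -1
         else (1 / target_fst - 1) * ((n_demes - 1) / n_demes)^2
  run <- function(mig, n, seed_off) with_seed(seed + seed_off, {
    theta <- exp(runif(n, log(mutation$theta_range[1]),
                       log(mutation$theta_range[2])))
    cpp_island_cloud(as.integer(sample_sizes), as.integer(n_demes), mig,
                     theta, model, mutation$gsm_p %||% 0.22)
  })
  if (calibrate && mig > 0) {
    pilot <- run(mig, pilot_loci, 1L)
    got <- mean(pilot[, 2], na.rm = TRUE)
    if (!is.na(got) && got > 1e-4 && got < 1)
      mig <- mig * (1 / target_fst - 1) / (1 / got - 1)
  }
  cloud <- run(mig, n_loci, 0L)
  df <- data.frame(He = cloud[, 1], Fst = cloud[, 2])
  dropped <- sum(is.na(df$Fst))
  df <- df[!is.na(df$Fst), , drop = FALSE]
  structure(df, class = c("neutral_cloud", "data.frame"),
            settings = list(target_fst = target_fst,
                            sample_sizes = as.integer(sample_sizes),
                            n_demes = n_demes, n_loci = n_loci,
                            mutation = mutation, mig_M = mig,
                            calibrated = calibrate, seed = seed,
                            monomorphic_dropped = dropped))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the neutral envelope from a simulated cloud
#'
#' Splits the He axis into equal-occupancy bins and takes the empirical
#' 0.5\%, 50\% and 99.5\% FST quantiles per bin (a 99\% interval); the curves
#' are interpolated piecewise-linearly between bin midpoints.
#'
#' @param cloud a [simulate_neutral_cloud()] result (or any data.frame with
#'   \code{He} and \code{Fst}).
#' @param n_bins number of equal-occupancy bins (>= 5).
#' @param min_bin bins with fewer points are merged with their neighbor.
#' @return object of class \code{neutral_envelope}: data.frame of bin
#'   midpoints with \code{lower}, \code{median}, \code{upper}; cloud settings
#'   carried through as attribute \code{"settings"}.
#' @export
build_envelope <- function(cloud, n_bins = 20L, min_bin = 50L) {
  stopifnot(nrow(cloud) > 0, n_bins >= 5L)
  n_bins <- min(n_bins, max(1L, nrow(cloud) %/% max(min_bin, 1L)))
  o <- order(cloud$He)
  he <- cloud$He[o]; fst <- cloud$Fst[o]
  idx <- cut(seq_along(he), breaks = n_bins, labels = FALSE)
  env <- do.call(rbind, lapply(split(seq_along(he), idx), function(ii) {
    q <- quantile(fst[ii], c(0.005, 0.5, 0.995), names = FALSE, type = 7)
    data.frame(He = mean(he[ii]), lower = q[1], median = q[2], upper = q[3],
               n = length(ii))
  }))
  rownames(env) <- NULL
  structure(env, class = c("neutral_envelope", "data.frame"),
            settings = attr(cloud, "settings"))
}

envelope_curve <- function(env, he, which) {
  approx(env$He, env[[which]], xout = he, rule = 2)$y
}

#' Classify observed loci against a neutral envelope
#'
#' A locus is \code{outlier_high} if its FST exceeds the interpolated upper
#' envelope curve at its heterozygosity, \code{outlier_low} symmetrically;
#' ties and everything inside the band are \code{neutral}. Loci whose He
#' falls outside the simulated range use the nearest curve value and are
#' flagged as extrapolated.
#'
#' @param obs data.frame with \code{locus}, \code{He}, \code{Fst} (see
#'   [observed_locus_stats()]).
#' @param envelope a [build_envelope()] result.
#' @return \code{obs} with added columns \code{lower}, \code{median},
#'   \code{upper}, \code{status}, \code{extrapolated}.
#' @export
classify_loci <- function(obs, envelope) {
  stopifnot(nrow(obs) >= 1)
  lo <- envelope_curve(envelope, obs$He, "lower")
  md <- envelope_curve(envelope, obs$He, "median")
  hi <- envelope_curve(envelope, obs$He, "upper")
  status <- rep("neutral", nrow(obs))
  status[obs$Fst > hi] <- "outlier_high"
  status[obs$Fst < lo] <- "outlier_low"
  status[is.na(obs$Fst)] <- NA_character_
  cbind(obs, lower = lo, median = md, upper = hi, status = status,
        extrapolated = obs$He < min(envelope$He) | obs$He > max(envelope$He))
}

# multi-locus GST restricted to a subset of loci
gst_subset <- function(freqs, pops, keep) {
  hh <- locus_hs_ht(freqs, pops)
  ok <- !is.na(hh[, "Ht"]) & hh[, "Ht"] > 0 & keep
  if (!any(ok)) return(NA_real_)
  sum(hh[ok, "Ht"] - hh[ok, "Hs"]) / sum(hh[ok, "Ht"])
}

scan_one_set <- function(ds, pops, n_demes, n_loci, mutation, n_bins, seed,
                         trim) {
  obs <- observed_locus_stats(ds, pops)
  freqs <- allele_frequencies(ds, subset = pops)
  sizes <- as.integer(table(factor(ds$populations, levels = pops)))
  target <- max(0, gst_subset(freqs, pops, rep(TRUE, nrow(obs))))
  run <- function(tfst, sd_off) {
    cloud <- simulate_neutral_cloud(tfst, sizes, n_demes = n_demes,
                                    n_loci = n_loci, mutation = mutation,
                                    seed = seed + sd_off)
    classify_loci(obs, build_envelope(cloud, n_bins = n_bins))
  }
  res <- run(target, 0L)
  target_used <- target
  if (trim && any(res$status != "neutral", na.rm = TRUE)) {
    keep <- res$status == "neutral" & !is.na(res$status)
    trimmed <- max(0, gst_subset(freqs, pops, keep))
    if (!is.na(trimmed) && abs(trimmed - target) > 1e-8) {
      res <- run(trimmed, 1L)
      target_used <- trimmed
    }
  }
  list(result = res, target_fst = target_used, target_fst_raw = target)
}

#' Three-set outlier scan with the resprouting-type decision rule
#'
#' Runs the outlier scan on three population sets — all populations, the
#' populations of group 1, and the populations of group 2, each against a
#' null calibrated to that set's own multi-locus FST — and reports the loci
#' that are outliers in the whole set but in neither within-group set (the
#' signature of selection associated with the group contrast rather than
#' with structure inside a group).
#'
#' @param ds a [genotype_dataset()] with group labels (or supply
#'   \code{groups}).
#' @param groups named character vector population -> group.
#' @param n_demes,n_loci,mutation,n_bins as in [simulate_neutral_cloud()] /
#'   [build_envelope()].
#' @param trim if \code{TRUE} (default), outlier candidates are removed once
#'   from the target-FST estimate and the scan re-run at the trimmed target.
#' @param side which envelope violations count as "outlier" in the decision
#'   rule: \code{"high"} (default; elevated differentiation, the signature of
#'   divergent selection on the group contrast) or \code{"both"} (also count
#'   low outliers, the balancing-selection side). Per-locus status tables
#'   always report both sides.
#' @param seed integer seed.
#' @return object of class \code{three_set_scan}: per-set classification
#'   tables (\code{all}, \code{group1}, \code{group2}), the per-set target
#'   FST values, and \code{selected} — the loci satisfying
#'   outlier(all) & !outlier(group1) & !outlier(group2).
#' @export
three_set_scan <- function(ds, groups = ds$groups, n_demes = 100L,
                           n_loci = 20000L,
                           mutation = list(model = "smm",
                                           theta_range = c(0.2, 30),
                                           gsm_p = 0.22),
                           n_bins = 20L, trim = TRUE,
                           side = c("high", "both"), seed = 1L) {
  side <- match.arg(side)
  gs <- grouping_sets(ds, groups)
  if (length(gs$pops1) < 2L || length(gs$pops2) < 2L)
    stop("both groups need at least 2 populations")
  sets <- list(all = pop_levels(ds), group1 = gs$pops1, group2 = gs$pops2)
  scans <- mapply(function(pops, off) {
    scan_one_set(ds, pops, n_demes, n_loci, mutation, n_bins,
                 seed + off, trim)
  }, sets, c(0L, 100L, 200L), SIMPLIFY = FALSE)
  is_out <- function(sc) {
    s <- sc$result$status
    if (side == "high") !is.na(s) & s == "outlier_high"
    else !is.na(s) & s != "neutral"
  }
  sel <- ds$loci[is_out(scans$all) & !is_out(scans$group1) &
                   !is_out(scans$group2)]
  structure(list(all = scans$all$result, group1 = scans$group1$result,
                 group2 = scans$group2$result,
                 targets = vapply(scans, `[[`, 0, "target_fst"),
                 groups = c(all = "all", group1 = gs$g1, group2 = gs$g2),
                 selected = sel),
            class = "three_set_scan")
}

#' @export
print.three_set_scan <- function(x, ...) {
  cat("three_set_scan: targets",
      paste(sprintf("%s=%.3f", names(x$targets), x$targets), collapse = ", "),
      "\n")
  cat("selected loci:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}
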