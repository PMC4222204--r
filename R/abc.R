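# Approximate Bayesian computation over three divergence-with-bottleneck
# demographic scenarios for two sampled populations (pop1 and pop2, e.g. the
# lignotuberous and epicormic clusters):
#   scenario 1 - pop1 ancestral, pop2 derived through a bottleneck;
#   scenario 2 - pop2 ancestral, pop1 derived through a bottleneck;
#   scenario 3 - both derived from an unsampled ancestor, each bottlenecked.
# Coalescent simulation uses a generalized stepwise mutation model with a
# single-nucleotide-indel side channel; scenario choice by rejection
# (direct) and multinomial-logistic posterior probabilities; parameter
# posteriors by weighted quantiles of accepted draws.

#' The three demographic scenario specifications
#'
#' @return list of three \code{scenario_spec} objects (ids 1-3) describing
#'   which sampled population is ancestral and where the bottleneck sits.
#' @export
abc_scenarios <- function() {
  mk <- function(id, ancestral, bottlenecked) {
    structure(list(id = id, ancestral = ancestral,
                   bottlenecked = bottlenecked),
              class = "scenario_spec")
  }
  list(mk(1L, "pop1", "pop2"),
       mk(2L, "pop2", "pop1"),
       mk(3L, "unsampled", c("pop1", "pop2")))
}

#' Prior specification for the demographic parameters
#'
#' Defaults: ancestral and derived effective sizes uniform on
#' 10,000-100,000; bottleneck size uniform on 10-100; bottleneck duration
#' uniform on 250-750 years (1-3 generations at a 250-year generation time);
#' divergence time normal with mean 25,000 and sd 5,000 years, truncated to
#' exceed the bottleneck duration; per-locus mutation rate uniform on
#' 1e-4 to 1e-3 per generation; geometric step parameter uniform on
#' 0.1-0.3; single-nucleotide-indel rate log-uniform on 1e-8 to 1e-5.
#'
#' @param N_anc,N_derived,Nb uniform ranges for the effective sizes.
#' @param db_years uniform range of the bottleneck duration (years).
#' @param t1_mean,t1_sd normal prior of the divergence time (years).
#' @param mu uniform range of the mutation rate.
#' @param gsm_p uniform range of the geometric step parameter.
#' @param sni log-uniform range of the indel rate.
#' @param generation_time years per generation.
#' @return list of class \code{prior_spec}.
#' @export
prior_spec <- function(N_anc = c(10000, 100000), N_derived = c(10000, 100000),
                       Nb = c(10, 100), db_years = c(250, 750),
                       t1_mean = 25000, t1_sd = 5000, mu = c(1e-4, 1e-3),
                       gsm_p = c(0.1, 0.3), sni = c(1e-8, 1e-5),
                       generation_time = 250) {
  structure(list(N_anc = N_anc, N_derived = N_derived, Nb = Nb,
                 db_years = db_years, t1_mean = t1_mean, t1_sd = t1_sd,
                 mu = mu, gsm_p = gsm_p, sni = sni,
                 generation_time = generation_time),
            class = "prior_spec")
}

years_to_gen <- function(years, generation_time) {
  pmax(1, round(years / generation_time))
}

#' Draw parameter vectors from the prior
#'
#' Independent draws from each prior; the divergence time is redrawn until
#' it exceeds the bottleneck duration (so the bottleneck fits inside the
#' derived-lineage interval). Times are also expressed in generations
#' (divided by the generation time and rounded, minimum 1).
#'
#' @param n number of draws.
#' @param priors a [prior_spec()].
#' @param seed integer seed (or \code{NULL} to use the current RNG state).
#' @return data.frame with columns \code{N1}, \code{N2}, \code{Nanc},
#'   \code{Nb}, \code{t1_years}, \code{db_years}, \code{t1_gen},
#'   \code{db_gen}, \code{mu}, \code{gsm_p}, \code{sni}.
#' @export
sample_prior <- function(n, priors = prior_spec(), seed = NULL) {
  with_seed(seed, {
    runifr <- function(r) runif(n, r[1], r[2])
    db <- runifr(priors$db_years)
    t1 <- rnorm(n, priors$t1_mean, priors$t1_sd)
    for (tries in 1:1000) {
      bad <- which(t1 <= db)
      if (!length(bad)) break
      t1[bad] <- rnorm(length(bad), priors$t1_mean, priors$t1_sd)
    }
    if (any(t1 <= db)) stop("t1 prior truncation failed to converge")
    data.frame(
      N1 = runifr(priors$N_derived), N2 = runifr(priors$N_derived),
      Nanc = runifr(priors$N_anc), Nb = runifr(priors$Nb),
      t1_years = t1, db_years = db,
      t1_gen = years_to_gen(t1, priors$generation_time),
      db_gen = years_to_gen(db, priors$generation_time),
      mu = runifr(priors$mu), gsm_p = runifr(priors$gsm_p),
      sni = exp(runif(n, log(priors$sni[1]), log(priors$sni[2]))))
  })
}

draw_matrix <- function(draws) {
  as.matrix(draws[, c("N1", "N2", "Nanc", "Nb", "t1_gen", "db_gen", "mu",
                      "gsm_p", "sni")])
}

#' Names of the summary statistics, in vector order
#' @return character vector of the 12 statistic names.
#' @export
summary_stat_names <- function() {
  c("A_pop1", "He_pop1", "sizevar_pop1", "gw_m_pop1",
    "A_pop2", "He_pop2", "sizevar_pop2", "gw_m_pop2",
    "fst", "jost_d", "das", "dmu2")
}

#' Simulate a two-population genotype dataset under a scenario
#'
#' Backward-in-time coalescent for the chosen scenario and parameter draw;
#' mutations follow the generalized stepwise model (geometric steps,
#' reflecting 40-state motif space) plus single-nucleotide indels; sampled
#' allele copies are paired at random into diploids.
#'
#' @param scenario scenario id (1, 2 or 3) or a \code{scenario_spec}.
#' @param draw one-row data.frame from [sample_prior()].
#' @param sample_sizes diploid sample sizes \code{c(n1, n2)}.
#' @param n_loci number of unlinked loci.
#' @param seed integer seed.
#' @return a [genotype_dataset()] with populations \code{pop1}, \code{pop2}.
#' @export
simulate_dataset <- function(scenario, draw, sample_sizes = c(25L, 25L),
                             n_loci = 11L, seed = 1L) {
  id <- if (inherits(scenario, "scenario_spec")) scenario$id else scenario
  stopifnot(nrow(draw) == 1L, all(sample_sizes >= 1L), n_loci >= 1L)
  m <- draw_matrix(draw)
  al <- with_seed(seed,
    cpp_sim_divergence(as.integer(sample_sizes[1]),
                       as.integer(sample_sizes[2]), as.integer(n_loci),
                       as.integer(id),
                       m[1, "N1"], m[1, "N2"], m[1, "Nanc"], m[1, "Nb"],
                       m[1, "t1_gen"], m[1, "db_gen"], m[1, "mu"],
                       m[1, "gsm_p"], m[1, "sni"]))
  n1 <- sample_sizes[1]; n2 <- sample_sizes[2]
  n <- n1 + n2
  calls <- array(NA_integer_, c(n, n_loci, 2))
  calls[, , 1] <- al[seq(1, 2 * n, by = 2), , drop = FALSE]
  calls[, , 2] <- al[seq(2, 2 * n, by = 2), , drop = FALSE]
  genotype_dataset(calls, sprintf("sim_i%03d", seq_len(n)),
                   rep(c("pop1", "pop2"), c(n1, n2)),
                   sprintf("locus%02d", seq_len(n_loci)))
}

#' Summary statistics of a two-population dataset
#'
#' Fixed-order vector: per population the mean number of alleles per locus,
#' mean unbiased expected heterozygosity, mean allele-size variance and mean
#' Garza-Williamson M; pairwise FST (Nei-Chesser), Jost's D, mean
#' shared-allele distance and the mean squared allele-size difference
#' (delta-mu squared). Individuals with any missing call are dropped (with a
#' warning) since the statistics are defined on complete genotypes.
#'
#' @param ds a [genotype_dataset()] with exactly 2 populations.
#' @return named numeric vector of length 12 (see [summary_stat_names()]).
#' @export
summary_stats <- function(ds) {
  pops <- pop_levels(ds)
  if (length(pops) != 2L) stop("summary_stats needs exactly 2 populations")
  miss <- apply(is.na(ds$calls[, , 1, drop = FALSE]), 1, any)
  if (any(miss)) {
    warning("dropping ", sum(miss), " individual(s) with missing calls")
    ds <- subset_individuals(ds, !miss)
  }
  o <- order(match(ds$populations, pops))
  ds <- subset_individuals(ds, o)
  n1 <- sum(ds$populations == pops[1]); n2 <- sum(ds$populations == pops[2])
  L <- length(ds$loci)
  al <- matrix(0L, 2L * (n1 + n2), L)
  al[seq(1, nrow(al), by = 2), ] <- ds$calls[, , 1]
  al[seq(2, nrow(al), by = 2), ] <- ds$calls[, , 2]
  setNames(as.numeric(cpp_summary_stats(al, n1, n2)), summary_stat_names())
}

#' Build an ABC reference table
#'
#' Simulates \code{n_per_scenario} datasets under each scenario with fresh
#' prior draws and records (scenario, parameters, summary statistics).
#' Work proceeds in chunks with per-chunk derived seeds, so a table is
#' reproducible for a given (seed, chunk_size) and can be built in parallel
#' by chunk.
#'
#' @param n_per_scenario records per scenario.
#' @param priors a [prior_spec()].
#' @param sample_sizes diploid sample sizes \code{c(n1, n2)}.
#' @param n_loci loci per simulated dataset.
#' @param seed integer seed.
#' @param chunk_size records per chunk.
#' @param progress print a line per chunk.
#' @return object of class \code{abc_reftable}: data.frame with
#'   \code{scenario}, the parameter columns, and the 12 statistic columns;
#'   settings stored in attribute \code{"settings"}.
#' @export
build_reference_table <- function(n_per_scenario, priors = prior_spec(),
                                  sample_sizes = c(25L, 25L), n_loci = 11L,
                                  seed = 1L, chunk_size = 2000L,
                                  progress = FALSE) {
  stopifnot(n_per_scenario >= 1L)
  out <- list()
  chunk_id <- 0L
  for (sc in 1:3) {
    done <- 0L
    while (done < n_per_scenario) {
      chunk_id <- chunk_id + 1L
      m <- min(chunk_size, n_per_scenario - done)
      cseed <- (as.integer(seed) + 7919L * chunk_id) %% .Machine$integer.max
      block <- with_seed(cseed, {
        draws <- sample_prior(m, priors)
        stats <- cpp_reference_block(rep(sc, m), draw_matrix(draws),
                                     as.integer(sample_sizes[1]),
                                     as.integer(sample_sizes[2]),
                                     as.integer(n_loci))
        colnames(stats) <- summary_stat_names()
        cbind(data.frame(scenario = sc), draws, as.data.frame(stats))
      })
      out[[length(out) + 1L]] <- block
      done <- done + m
      if (progress)
        message(sprintf("scenario %d: %d / %d", sc, done, n_per_scenario))
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  structure(tab, class = c("abc_reftable", "data.frame"),
            settings = list(n_per_scenario = n_per_scenario,
                            sample_sizes = as.integer(sample_sizes),
                            n_loci = n_loci, seed = seed,
                            chunk_size = chunk_size, priors = priors))
}

stat_cols <- function(table) as.matrix(table[, summary_stat_names()])

# columnwise robust standardization for ABC distances; constant columns drop
std_scales <- function(stats) {
  s <- apply(stats, 2, mad)
  zero <- s == 0
  s[zero] <- apply(stats[, zero, drop = FALSE], 2, sd)
  s[s == 0] <- NA # constant column: excluded from the distance
  s
}

abc_distances <- function(obs, table) {
  stats <- stat_cols(table)
  sc <- std_scales(stats)
  use <- !is.na(sc)
  z <- sweep(stats[, use, drop = FALSE], 2, sc[use], "/")
  zo <- obs[use] / sc[use]
  sqrt(colSums((t(z) - zo)^2))
}

#' Direct (rejection) scenario posterior probabilities
#'
#' Standardizes the summary statistics by their table-wide median absolute
#' deviation, ranks records by Euclidean distance to the observed vector,
#' and returns the scenario proportions among the closest records (ties at
#' the cutoff all included).
#'
#' @param obs observed summary-statistic vector (see [summary_stats()]).
#' @param table an [build_reference_table()] result.
#' @param n_closest number of accepted records.
#' @return list: \code{prob} (named per-scenario probabilities summing to
#'   1), \code{chosen}, \code{n_accepted}.
#' @export
direct_posterior <- function(obs, table, n_closest = 1500L) {
  stopifnot(n_closest >= 1L, n_closest <= nrow(table))
  d <- abc_distances(obs, table)
  cut <- sort(d, partial = n_closest)[n_closest]
  acc <- which(d <= cut)
  pr <- vapply(1:3, function(s) mean(table$scenario[acc] == s), 0)
  names(pr) <- paste0("scenario", 1:3)
  list(prob = pr, chosen = which.max(pr), n_accepted = length(acc))
}

#' Logistic-regression scenario posterior probabilities
#'
#' Multinomial logistic regression of the scenario id on the differences
#' (statistics - observed) over the closest records; the posterior
#' probabilities are the fitted values at difference zero. The fit is
#' ridge-stabilized (weight decay), so separable neighborhoods remain
#' estimable; a single-scenario neighborhood falls back to the direct
#' estimate with a warning.
#'
#' @inheritParams direct_posterior
#' @param n_closest regression neighborhood size.
#' @param decay ridge penalty passed to \code{nnet::multinom}.
#' @return as [direct_posterior()], plus \code{method}.
#' @export
logistic_posterior <- function(obs, table, n_closest = 15000L,
                               decay = 0.01) {
  stopifnot(n_closest >= 1L, n_closest <= nrow(table))
  d <- abc_distances(obs, table)
  cut <- sort(d, partial = n_closest)[n_closest]
  acc <- which(d <= cut)
  sub <- table[acc, , drop = FALSE]
  present <- sort(unique(sub$scenario))
  if (length(present) < 2L) {
    warning("single-scenario neighborhood; returning direct estimate")
    out <- direct_posterior(obs, table, n_closest = min(n_closest,
                                                        nrow(table)))
    out$method <- "direct_fallback"
    return(out)
  }
  stats <- stat_cols(sub)
  sc <- std_scales(stat_cols(table))
  use <- !is.na(sc)
  X <- sweep(sweep(stats[, use, drop = FALSE], 2, obs[use], "-"),
             2, sc[use], "/")
  df <- data.frame(scenario = factor(sub$scenario, levels = present), X)
  fit <- nnet::multinom(scenario ~ ., data = df, decay = decay,
                        trace = FALSE, maxit = 500)
  p0 <- predict(fit, newdata = data.frame(t(setNames(rep(0, ncol(X)),
                                                     colnames(X)))),
                type = "probs")
  pr <- setNames(rep(0, 3), paste0("scenario", 1:3))
  if (length(present) == 2L) {
    pr[present[2]] <- p0; pr[present[1]] <- 1 - p0
  } else pr[present] <- as.numeric(p0)
  list(prob = pr, chosen = unname(which.max(pr)), n_accepted = length(acc),
       method = "logistic")
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], 0)
}

#' Posterior parameter quantiles under a chosen scenario
#'
#' Restricts the reference table to one scenario, accepts the closest
#' records, and reports weighted quantiles of the accepted parameter draws
#' (Epanechnikov weights in distance, or uniform weights), optionally after
#' local-linear regression adjustment of the draws toward the observed
#' statistics.
#'
#' @inheritParams direct_posterior
#' @param scenario scenario id to condition on.
#' @param n_closest accepted records.
#' @param adjust \code{"none"} or \code{"loclinear"}.
#' @param weighting \code{"epanechnikov"} or \code{"uniform"}.
#' @param probs quantiles to report.
#' @param params parameter columns to summarize.
#' @return data.frame: one row per parameter with the requested quantiles.
#' @export
posterior_parameters <- function(obs, table, scenario, n_closest = 1500L,
                                 adjust = c("none", "loclinear"),
                                 weighting = c("epanechnikov", "uniform"),
                                 probs = c(0.05, 0.5, 0.95),
                                 params = c("N1", "N2", "Nanc", "Nb",
                                            "t1_years", "db_years", "mu")) {
  adjust <- match.arg(adjust)
  weighting <- match.arg(weighting)
  sub <- table[table$scenario == scenario, , drop = FALSE]
  if (nrow(sub) < n_closest)
    stop("scenario ", scenario, " has fewer records than n_closest")
  d <- abc_distances(obs, sub)
  cut <- sort(d, partial = n_closest)[n_closest]
  acc <- which(d <= cut)
  da <- d[acc]
  w <- if (weighting == "epanechnikov") {
    dmax <- max(da) * (1 + 1e-12)
    1 - (da / dmax)^2
  } else rep(1, length(acc))
  w[w <= 0] <- min(w[w > 0]) / 2
  theta <- as.matrix(sub[acc, params, drop = FALSE])
  if (adjust == "loclinear") {
    sc <- std_scales(stat_cols(table))
    use <- !is.na(sc)
    X <- sweep(sweep(stat_cols(sub)[acc, use, drop = FALSE], 2, obs[use],
                     "-"), 2, sc[use], "/")
    fit <- tryCatch(stats::lm.wfit(cbind(1, X), theta, w),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      warning("local-linear adjustment singular; using unadjusted draws")
    } else {
      beta <- fit$coefficients[-1, , drop = FALSE]
      theta <- theta - X %*% beta
    }
  }
  out <- data.frame(parameter = params,
                    t(apply(theta, 2, weighted_quantile, w = w,
                            probs = probs)), row.names = NULL)
  colnames(out)[-1] <- paste0("q", probs * 100)
  out
}

#' Confidence evaluation of the scenario choice
#'
#' Leave-one-out style error rates from pseudo-observed datasets: records
#' are drawn from the reference table itself (their statistics are prior-
#' predictive draws of their scenario), each is classified against the
#' remaining records, and misclassification rates are tabulated.
#'
#' @param table an [build_reference_table()] result.
#' @param n_pods pseudo-observed datasets per scenario (>= 50 in total
#'   recommended).
#' @param n_closest acceptance count for the classifier.
#' @param method \code{"direct"} or \code{"logistic"}.
#' @param seed integer seed.
#' @return list: \code{confusion} (3 x 3 true x chosen counts),
#'   \code{type1} per scenario (P(not chosen | true)), \code{type2} per
#'   scenario (P(chosen | not true)), and \code{confidence} per scenario
#'   (P(true | chosen), the posterior predictive confidence of a choice).
#' @export
confidence_evaluation <- function(table, n_pods = 100L, n_closest = 1500L,
                                  method = c("direct", "logistic"),
                                  seed = 1L) {
  method <- match.arg(method)
  cls <- if (method == "direct") {
    function(obs, tab) direct_posterior(obs, tab, n_closest)$chosen
  } else {
    function(obs, tab) logistic_posterior(obs, tab, n_closest)$chosen
  }
  idx <- with_seed(seed, {
    unlist(lapply(1:3, function(s)
      sample(which(table$scenario == s), n_pods)))
  })
  stats <- stat_cols(table)
  chosen <- integer(length(idx))
  for (j in seq_along(idx)) {
    rest <- table[-idx[j], , drop = FALSE]
    chosen[j] <- cls(stats[idx[j], ], rest)
  }
  truth <- table$scenario[idx]
  confusion <- table(factor(truth, 1:3), factor(chosen, 1:3))
  dimnames(confusion) <- list(true = 1:3, chosen = 1:3)
  type1 <- 1 - diag(confusion) / rowSums(confusion)
  conf <- diag(confusion) / pmax(colSums(confusion), 1)
  type2 <- vapply(1:3, function(s)
    sum(confusion[-s, s]) / sum(confusion[-s, ]), 0)
  list(confusion = confusion,
       type1 = setNames(as.numeric(type1), paste0("scenario", 1:3)),
       type2 = setNames(type2, paste0("scenario", 1:3)),
       confidence = setNames(as.numeric(conf), paste0("scenario", 1:3)))
}
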