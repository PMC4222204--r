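# Bayesian model-based clustering of individuals (admixture model, Gibbs
# sampling) and Evanno delta-K selection of the number of clusters. This is a
# deliberately minimal admixture sampler: uniform admixture hyperparameter
# (alpha fixed at 1, no updating), independent cluster allele frequencies
# with a Dirichlet(lambda) prior, no linkage model.

# encode calls as 0-based allele indices per locus; -1 = missing
encode_genotypes <- function(ds) {
  n <- length(ds$individuals); L <- length(ds$loci)
  geno <- matrix(-1L, n, 2L * L)
  n_alleles <- integer(L)
  for (l in seq_len(L)) {
    a1 <- ds$calls[, l, 1]; a2 <- ds$calls[, l, 2]
    states <- sort(unique(c(a1, a2)))
    states <- states[!is.na(states)]
    n_alleles[l] <- max(length(states), 1L)
    geno[, 2L * l - 1L] <- ifelse(is.na(a1), -1L, match(a1, states) - 1L)
    geno[, 2L * l] <- ifelse(is.na(a2), -1L, match(a2, states) - 1L)
  }
  list(geno = geno, n_alleles = n_alleles)
}

#' Fit the admixture clustering model for a fixed K
#'
#' Gibbs sampler alternating cluster assignment of each allele copy,
#' Dirichlet updates of cluster allele frequencies, and Dirichlet updates of
#' each individual's admixture proportions. Returns the posterior-mean
#' admixture matrix Q and the run's ln P(X|K) estimate
#' \code{mean(lnL) - var(lnL)/2}.
#'
#' @param ds a [genotype_dataset()].
#' @param K number of clusters (>= 1).
#' @param burn_in,n_iter burn-in and total sweeps (\code{n_iter > burn_in}).
#' @param alpha admixture Dirichlet hyperparameter (fixed).
#' @param lambda allele-frequency Dirichlet hyperparameter.
#' @param seed integer seed.
#' @param thin_trace keep every \code{thin_trace}-th log-likelihood value.
#' @return object of class \code{admixture_fit}: \code{K}, \code{Q}
#'   (individuals x K, rows sum to 1), \code{lnPK}, \code{mean_ll},
#'   \code{var_ll}, \code{trace}, and the run settings.
#' @export
fit_admixture <- function(ds, K, burn_in = 5000L, n_iter = 50000L,
                          alpha = 1, lambda = 1, seed = 1L,
                          thin_trace = 10L) {
  enc <- encode_genotypes(ds)
  fit <- with_seed(seed, cpp_admixture_gibbs(enc$geno, enc$n_alleles,
                                             as.integer(K),
                                             as.integer(burn_in),
                                             as.integer(n_iter),
                                             alpha, lambda,
                                             as.integer(thin_trace)))
  rownames(fit$Q) <- ds$individuals
  structure(list(K = K, Q = fit$Q, lnPK = fit$lnPK, mean_ll = fit$mean_ll,
                 var_ll = fit$var_ll, trace = fit$trace,
                 settings = list(burn_in = burn_in, n_iter = n_iter,
                                 alpha = alpha, lambda = lambda,
                                 seed = seed)),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K = %d, ln P(X|K) = %.1f\n", x$K, x$lnPK))
  invisible(x)
}

#' Hard cluster assignment from an admixture fit
#' @param fit an [fit_admixture()] result.
#' @return integer vector: the maximum-membership cluster per individual.
#' @export
cluster_assignment <- function(fit) {
  unname(apply(fit$Q, 1, which.max))
}

#' Agreement between clusters and reference labels
#'
#' Fraction of individuals whose hard cluster assignment matches a reference
#' partition, maximized over the assignment of cluster labels to reference
#' labels (greedy matching on the contingency table).
#'
#' @param fit an [fit_admixture()] result.
#' @param labels reference labels, one per individual.
#' @return agreement fraction in [0, 1].
#' @export
cluster_agreement <- function(fit, labels) {
  cl <- cluster_assignment(fit)
  tab <- table(cl, labels)
  matched <- 0
  while (nrow(tab) > 0 && ncol(tab) > 0) {
    ij <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    matched <- matched + tab[ij[1], ij[2]]
    tab <- tab[-ij[1], -ij[2], drop = FALSE]
  }
  matched / length(cl)
}

#' Scan K with replicate runs
#'
#' Fits the admixture model for each K in a range with several independently
#' seeded runs, collecting the ln P(X|K) table that Evanno's delta-K needs.
#'
#' @inheritParams fit_admixture
#' @param K_range integer vector of K values (consecutive for delta-K).
#' @param n_runs replicate runs per K (>= 2 for delta-K).
#' @param keep_fits keep the full fit of each run (memory permitting).
#' @return object of class \code{structure_scan}: \code{lnp} data.frame
#'   (\code{K}, \code{run}, \code{lnP}), and \code{fits} — per K, the run
#'   with the highest ln P(X|K) (all runs when \code{keep_fits = TRUE}).
#' @export
structure_scan <- function(ds, K_range = 1:6, n_runs = 5L, burn_in = 5000L,
                           n_iter = 50000L, alpha = 1, lambda = 1, seed = 1L,
                           keep_fits = FALSE) {
  rows <- list(); best <- list(); all_fits <- list()
  for (K in K_range) {
    fits <- lapply(seq_len(n_runs), function(r) {
      fit_admixture(ds, K, burn_in = burn_in, n_iter = n_iter, alpha = alpha,
                    lambda = lambda, seed = seed + 1000L * K + r)
    })
    lnp <- vapply(fits, `[[`, 0, "lnPK")
    rows[[length(rows) + 1L]] <- data.frame(K = K, run = seq_len(n_runs),
                                            lnP = lnp)
    best[[as.character(K)]] <- fits[[which.max(lnp)]]
    if (keep_fits) all_fits[[as.character(K)]] <- fits
  }
  structure(list(lnp = do.call(rbind, rows),
                 fits = if (keep_fits) all_fits else best),
            class = "structure_scan")
}

#' Evanno delta-K
#'
#' Second-difference statistic over mean ln P(X|K):
#' \deqn{\Delta K = |\bar L(K+1) - 2 \bar L(K) + \bar L(K-1)| / sd(L(K))}
#' undefined at the endpoints of the scanned range. A zero run-to-run
#' standard deviation yields an infinite delta-K with a warning.
#'
#' @param lnp a \code{structure_scan} result or a data.frame with columns
#'   \code{K}, \code{run}, \code{lnP} (>= 3 consecutive K, >= 2 runs each).
#' @return data.frame: \code{K}, \code{mean_lnP}, \code{sd_lnP},
#'   \code{delta_K}.
#' @export
evanno_delta_k <- function(lnp) {
  if (inherits(lnp, "structure_scan")) lnp <- lnp$lnp
  ks <- sort(unique(lnp$K))
  if (length(ks) < 3L) stop("need at least 3 consecutive K values")
  if (any(diff(ks) != 1L)) stop("K values must be consecutive")
  runs <- table(lnp$K)
  if (any(runs < 2L)) stop("need at least 2 runs per K")
  mu <- tapply(lnp$lnP, lnp$K, mean)[as.character(ks)]
  sdv <- tapply(lnp$lnP, lnp$K, sd)[as.character(ks)]
  dk <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-c(1, length(ks))]) {
    num <- abs(mu[i + 1] - 2 * mu[i] + mu[i - 1])
    if (sdv[i] == 0) {
      warning("zero sd of lnP at K = ", ks[i], "; delta-K infinite")
      dk[i] <- Inf
    } else dk[i] <- num / sdv[i]
  }
  data.frame(K = ks, mean_lnP = unname(mu), sd_lnP = unname(sdv),
             delta_K = dk, row.names = NULL)
}

#' Best K by Evanno delta-K
#' @param lnp as in [evanno_delta_k()].
#' @return the K with the largest delta-K (interior K only).
#' @export
best_k <- function(lnp) {
  ev <- evanno_delta_k(lnp)
  ev$K[which.max(ev$delta_K)]
}
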