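# End-to-end orchestration: diversity -> differentiation -> per-locus
# differentiation with bootstrap -> clustering -> outlier scan -> ABC, with
# per-stage TSV/JSON artifacts and a consolidated JSON report. The exported
# functions are the package's interface; run_all() simply sequences them.

#' Assemble a run configuration
#'
#' @param input a [genotype_dataset()], or a path to a GenePop (\code{.gen})
#'   or tabular (\code{.tsv}) genotype file.
#' @param group_map named character vector population -> group, or a path to
#'   a two-column TSV ([read_group_map()]); \code{NULL} disables the stages
#'   that need groups.
#' @param out_dir output directory (created if missing).
#' @param seed master seed; stages derive their own from it.
#' @param n_standardize optional common sample size for the diversity table.
#' @param statistic pairwise statistic for the matrix and block summaries.
#' @param n_boot bootstrap replicates for per-locus differentiation.
#' @param outlier list of [three_set_scan()] settings (set \code{NULL} to
#'   skip).
#' @param clustering list of [structure_scan()] settings (set \code{NULL} to
#'   skip).
#' @param abc list of ABC settings: \code{n_per_scenario},
#'   \code{sample_sizes}, \code{n_closest_direct}, \code{n_closest_logistic}
#'   (set \code{NULL} to skip). Acceptance counts default to the fractions
#'   1500/6e6 and 15000/6e6 of the table size, with a floor of 100.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(input, group_map = NULL, out_dir = tempfile("msatpop"),
                       seed = 1L, n_standardize = NULL,
                       statistic = "fst_prime", n_boot = 1000L,
                       outlier = list(), clustering = list(), abc = list()) {
  structure(list(input = input, group_map = group_map, out_dir = out_dir,
                 seed = as.integer(seed), n_standardize = n_standardize,
                 statistic = statistic, n_boot = n_boot, outlier = outlier,
                 clustering = clustering, abc = abc),
            class = "run_config")
}

load_input <- function(input, groups) {
  if (inherits(input, "genotype_dataset")) {
    if (!is.null(groups)) input$groups <- groups[unique(input$populations)]
    return(input)
  }
  if (grepl("\\.tsv$", input)) read_genotypes_tsv(input, groups = groups)
  else read_genepop(input, groups = groups)
}

#' Run the full analysis pipeline
#'
#' Sequences every stage on one dataset and writes per-stage artifacts
#' (TSV/JSON) plus a consolidated \code{report.json} into the configured
#' output directory. Stages that need group labels are skipped with a notice
#' when no mapping is given. Rerunning with the same configuration
#' reproduces identical numbers.
#'
#' @param config a [run_config()].
#' @return (invisibly) the report list.
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- config$group_map
  groups <- if (is.character(gm) && length(gm) == 1L && is.null(names(gm)))
    read_group_map(gm) else gm
  ds <- load_input(config$input, groups)
  groups <- ds$groups
  seed <- config$seed
  report <- list(seed = seed, n_individuals = length(ds$individuals),
                 n_populations = length(unique(ds$populations)),
                 n_loci = length(ds$loci))
  out <- function(...) file.path(config$out_dir, ...)

  # diversity
  div <- diversity_table(ds, n_standardize = config$n_standardize,
                         seed = seed)
  write.table(div, out("diversity.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  report$diversity <- div

  # pairwise differentiation + block summary
  pw <- pairwise_matrix(ds, config$statistic)
  write.table(round(pw$matrix, 4), out("pairwise.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  report$pairwise_statistic <- config$statistic
  if (!is.null(groups)) {
    blk <- block_summary(pw, groups)
    write.table(blk, out("block_summary.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$block_summary <- blk
  } else message("no group mapping: block summary skipped")

  # per-locus differentiation with bootstrap bounds
  if (!is.null(groups)) {
    bs <- bootstrap_ci(ds, groups, n_boot = config$n_boot, seed = seed + 1L)
    tab <- cbind(bs$point,
                 setNames(bs$lower[-1], paste0(colnames(bs$lower)[-1], "_lo")),
                 setNames(bs$upper[-1], paste0(colnames(bs$upper)[-1], "_hi")))
    write.table(tab, out("locus_differentiation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$locus_differentiation <- tab
  }

  # clustering
  if (!is.null(config$clustering)) {
    cs <- config$clustering
    scan <- structure_scan(ds, K_range = cs$K_range %||% 1:6,
                           n_runs = cs$n_runs %||% 5L,
                           burn_in = cs$burn_in %||% 5000L,
                           n_iter = cs$n_iter %||% 50000L,
                           seed = seed + 2L)
    ev <- evanno_delta_k(scan)
    write.table(scan$lnp, out("clustering_lnp.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ev, out("clustering_evanno.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    kbest <- best_k(scan)
    fit <- scan$fits[[as.character(kbest)]]
    qtab <- data.frame(individual = ds$individuals,
                       population = ds$populations, fit$Q)
    write.table(qtab, out("clustering_q.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$clustering <- list(best_k = kbest, evanno = ev)
  }

  # outlier scan
  if (!is.null(config$outlier) && !is.null(groups)) {
    os <- config$outlier
    scan <- three_set_scan(ds, groups,
                           n_demes = os$n_demes %||% 100L,
                           n_loci = os$n_loci %||% 20000L,
                           n_bins = os$n_bins %||% 20L,
                           trim = os$trim %||% TRUE,
                           seed = seed + 3L)
    for (s in c("all", "group1", "group2"))
      write.table(scan[[s]], out(paste0("outliers_", s, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    report$outliers <- list(selected = scan$selected,
                            targets = as.list(scan$targets))
  }

  # ABC scenario comparison on the two pooled groups
  if (!is.null(config$abc) && !is.null(groups)) {
    ab <- config$abc
    pooled <- pool_groups(ds, groups)
    obs <- summary_stats(pooled)
    sizes <- ab$sample_sizes %||%
      as.integer(table(factor(pooled$populations,
                              levels = unique(pooled$populations))))
    nps <- ab$n_per_scenario %||% 20000L
    tabsize <- 3 * nps
    ncd <- ab$n_closest_direct %||% max(100L, round(tabsize * 1500 / 6e6))
    ncl <- ab$n_closest_logistic %||% max(100L, round(tabsize * 15000 / 6e6))
    reft <- build_reference_table(nps, priors = ab$priors %||% prior_spec(),
                                  sample_sizes = sizes,
                                  n_loci = length(ds$loci),
                                  seed = seed + 4L)
    dp <- direct_posterior(obs, reft, n_closest = ncd)
    lp <- logistic_posterior(obs, reft, n_closest = ncl)
    post <- posterior_parameters(obs, reft, lp$chosen,
                                 n_closest = min(ncd,
                                                 sum(reft$scenario ==
                                                       lp$chosen)))
    write.table(post, out("abc_parameters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$abc <- list(observed = as.list(obs),
                       direct = as.list(dp$prob),
                       logistic = as.list(lp$prob),
                       chosen = lp$chosen,
                       parameters = post)
  } else if (!is.null(config$abc) && is.null(groups)) {
    message("no group mapping: ABC stage skipped")
  }

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(report)
}
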