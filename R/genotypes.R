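#' Construct a diploid microsatellite genotype dataset
#'
#' The central container of the package: allele-length calls for a set of
#' diploid individuals at a set of codominant loci, with a population label
#' per individual and, optionally, a phenotype-group label per population
#' (e.g. \code{"lignotuberous"} vs \code{"epicormic"}).
#'
#' @param calls integer array of dimension \code{c(n_individuals, n_loci, 2)}:
#'   the two allele states (positive integers, e.g. repeat-scaled fragment
#'   lengths) per individual and locus. A missing call is \code{NA} in both
#'   slots; half-missing calls are promoted to fully missing.
#' @param individuals character vector of individual ids.
#' @param populations character vector, one population id per individual.
#' @param loci character vector of locus names.
#' @param groups optional named character vector mapping population id to
#'   group label.
#' @return An object of class \code{genotype_dataset}.
#' @export
genotype_dataset <- function(calls, individuals, populations, loci,
                             groups = NULL) {
  if (length(dim(calls)) != 3L || dim(calls)[3] != 2L)
    stop("`calls` must be an n x loci x 2 array")
  n <- dim(calls)[1]; L <- dim(calls)[2]
  if (n < 1L || L < 1L) stop("need at least 1 individual and 1 locus")
  if (length(individuals) != n) stop("individuals/calls mismatch")
  if (length(populations) != n) stop("populations/calls mismatch")
  if (length(loci) != L) stop("loci/calls mismatch")
  storage.mode(calls) <- "integer"
  # promote half-missing to missing
  miss <- is.na(calls[, , 1, drop = FALSE]) | is.na(calls[, , 2, drop = FALSE])
  if (any(miss)) {
    m1 <- calls[, , 1]; m2 <- calls[, , 2]
    m1[miss[, , 1]] <- NA_integer_; m2[miss[, , 1]] <- NA_integer_
    calls[, , 1] <- m1; calls[, , 2] <- m2
  }
  if (any(calls <= 0L, na.rm = TRUE)) stop("allele states must be positive")
  populations <- as.character(populations)
  if (!is.null(groups)) {
    groups <- setNames(as.character(groups), names(groups))
    bad <- setdiff(unique(populations), names(groups))
    if (length(bad))
      stop("groups missing for population(s): ", paste(bad, collapse = ", "))
  }
  dimnames(calls) <- list(individuals, loci, NULL)
  structure(list(individuals = as.character(individuals),
                 populations = populations,
                 loci = as.character(loci),
                 calls = calls,
                 groups = groups),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals, %d populations, %d loci\n",
              length(x$individuals), length(unique(x$populations)),
              length(x$loci)))
  if (!is.null(x$groups)) {
    tab <- table(x$groups[unique(x$populations)])
    cat("groups:", paste(sprintf("%s=%d", names(tab), as.vector(tab)),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

pop_levels <- function(ds) unique(ds$populations)

#' Subset a genotype dataset by individuals
#' @param ds a \code{genotype_dataset}.
#' @param idx integer or logical index over individuals.
#' @return a \code{genotype_dataset} restricted to the selected individuals.
#' @export
subset_individuals <- function(ds, idx) {
  genotype_dataset(ds$calls[idx, , , drop = FALSE],
                   ds$individuals[idx], ds$populations[idx],
                   ds$loci, ds$groups)
}

#' Read a GenePop genotype file
#'
#' Parses the GenePop dialect for diploid data with 2- or 3-digit allele
#' coding. Populations are delimited by \code{POP} lines; individual labels
#' may be separated from genotypes by a comma or a tab. The missing code
#' (\code{00}/\code{000} per allele) becomes a missing call.
#'
#' @param path file path.
#' @param pop_names optional character vector naming the POP blocks; defaults
#'   to \code{pop1..popK}, or to the label of each block's last individual
#'   when \code{pop_names = "last"}.
#' @param groups optional named character vector (population -> group label),
#'   e.g. from [read_group_map()].
#' @return a [genotype_dataset()].
#' @export
read_genepop <- function(path, pop_names = NULL, groups = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("not a GenePop file (too short): ", path)
  lines <- lines[nzchar(trimws(lines))]
  # line 1: title. Loci: either one comma-separated line or one per line
  # until the first POP.
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L)
    stop("malformed GenePop: no POP delimiter after locus list")
  locus_lines <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("malformed GenePop: empty locus list")
  L <- length(loci)

  block <- cumsum(is_pop)
  ind_lines <- which(!is_pop & seq_along(lines) > first_pop)
  if (!length(ind_lines)) stop("malformed GenePop: no individuals")
  n <- length(ind_lines)
  calls <- array(NA_integer_, c(n, L, 2))
  ids <- character(n); popi <- integer(n)
  for (r in seq_along(ind_lines)) {
    li <- ind_lines[r]
    txt <- lines[li]
    # label separator: first comma, else first tab
    sep <- regexpr(",", txt, fixed = TRUE)
    if (sep < 0) sep <- regexpr("\t", txt, fixed = TRUE)
    if (sep < 0)
      stop("parse error at line ", li, ": no ',' or tab after individual label")
    ids[r] <- trimws(substr(txt, 1, sep - 1))
    gstr <- strsplit(trimws(substr(txt, sep + 1, nchar(txt))), "[ \t]+")[[1]]
    gstr <- gstr[nzchar(gstr)]
    if (length(gstr) != L)
      stop("structural error at line ", li, ": expected ", L,
           " loci, found ", length(gstr))
    w <- nchar(gstr)
    if (!all(w %in% c(4L, 6L)) || length(unique(w)) != 1L)
      stop("parse error at line ", li,
           ": genotypes must be uniformly 4- or 6-digit")
    half <- w[1] / 2L
    a1 <- suppressWarnings(as.integer(substr(gstr, 1, half)))
    a2 <- suppressWarnings(as.integer(substr(gstr, half + 1, w[1])))
    if (anyNA(a1) || anyNA(a2))
      stop("parse error at line ", li, ": non-numeric allele code")
    a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
    calls[r, , 1] <- a1; calls[r, , 2] <- a2
    popi[r] <- block[li]
  }
  popi <- match(popi, unique(popi))
  k <- max(popi)
  nm <- if (is.null(pop_names)) paste0("pop", seq_len(k))
        else if (identical(pop_names, "last"))
          vapply(seq_len(k), function(j) ids[max(which(popi == j))], "")
        else {
          if (length(pop_names) != k)
            stop("pop_names has length ", length(pop_names), ", need ", k)
          pop_names
        }
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  genotype_dataset(calls, ids, nm[popi], loci, groups = groups)
}

#' Write a GenePop genotype file
#'
#' Emits canonical 3-digit GenePop: title line, one locus name per line, one
#' \code{POP} block per population in dataset order, and \code{000} for
#' missing alleles.
#'
#' @param ds a [genotype_dataset()].
#' @param path output file path.
#' @param title title line content.
#' @return invisibly, `path`.
#' @export
write_genepop <- function(ds, path, title = "msatpop export") {
  if (!length(ds$loci)) stop("empty locus list")
  if (any(ds$calls > 999L, na.rm = TRUE))
    stop("encoding error: allele state > 999 cannot be written as 3-digit")
  a1 <- ds$calls[, , 1, drop = FALSE]; a2 <- ds$calls[, , 2, drop = FALSE]
  a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
  gs <- matrix(sprintf("%03d%03d", a1, a2), nrow = dim(ds$calls)[1])
  out <- c(title, ds$loci)
  for (p in pop_levels(ds)) {
    out <- c(out, "POP")
    rows <- which(ds$populations == p)
    out <- c(out, vapply(rows, function(r)
      paste0(ds$individuals[r], " ,  ", paste(gs[r, ], collapse = " ")), ""))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a plain tabular genotype file
#'
#' Columns: \code{individual}, \code{population}, then one column per locus
#' with \code{"a1/a2"} cells and \code{"./."} for missing.
#'
#' @inheritParams read_genepop
#' @return a [genotype_dataset()].
#' @export
read_genotypes_tsv <- function(path, groups = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 3L) stop("tabular genotypes need individual, population and",
                          " at least one locus column")
  loci <- colnames(df)[-(1:2)]
  n <- nrow(df)
  calls <- array(NA_integer_, c(n, length(loci), 2))
  for (j in seq_along(loci)) {
    parts <- strsplit(df[[j + 2L]], "/", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) stop("parse error: malformed genotype in row ", bad[1],
                          ", locus ", loci[j])
    m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
    m[m == "."] <- NA
    calls[, j, 1] <- suppressWarnings(as.integer(m[, 1]))
    calls[, j, 2] <- suppressWarnings(as.integer(m[, 2]))
  }
  genotype_dataset(calls, df[[1]], df[[2]], loci, groups = groups)
}

#' Write the plain tabular genotype dialect
#' @inheritParams write_genepop
#' @return invisibly, `path`.
#' @export
write_genotypes_tsv <- function(ds, path) {
  a1 <- ds$calls[, , 1]; a2 <- ds$calls[, , 2]
  cell <- matrix(paste0(ifelse(is.na(a1), ".", a1), "/",
                        ifelse(is.na(a2), ".", a2)),
                 nrow = length(ds$individuals))
  df <- data.frame(individual = ds$individuals, population = ds$populations,
                   cell, check.names = FALSE)
  colnames(df)[-(1:2)] <- ds$loci
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population-to-group mapping
#'
#' Two-column TSV (\code{population}, \code{group}); phenotype-group labels
#' are kept out of the GenePop file itself.
#'
#' @param path file path.
#' @return named character vector: population -> group.
#' @export
read_group_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", colClasses = "character")
  setNames(df[[2]], df[[1]])
}

#' Per-population allele frequencies
#'
#' Counts allele states over the \code{2n} non-missing allele copies at each
#' (population, locus) and normalizes to relative frequencies; \code{n} is the
#' number of non-missing diploid individuals. A (population, locus) with no
#' data has \code{n = 0} and an all-zero frequency row, which downstream
#' statistics treat as undefined, not zero.
#'
#' @param ds a [genotype_dataset()].
#' @param subset optional character vector of population ids to restrict to.
#' @return an object of class \code{allele_freq_table}: list with
#'   \code{pops}, \code{loci}, \code{n} (pops x loci matrix of diploid sample
#'   sizes) and \code{freq} (per locus, a pops x alleles frequency matrix
#'   whose column names are the allele states).
#' @export
allele_frequencies <- function(ds, subset = NULL) {
  pops <- if (is.null(subset)) pop_levels(ds) else {
    bad <- setdiff(subset, ds$populations)
    if (length(bad)) stop("unknown population(s): ", paste(bad, collapse = ", "))
    subset
  }
  keep <- ds$populations %in% pops
  popf <- factor(ds$populations[keep], levels = pops)
  L <- length(ds$loci)
  nmat <- matrix(0L, length(pops), L, dimnames = list(pops, ds$loci))
  freq <- vector("list", L); names(freq) <- ds$loci
  for (l in seq_len(L)) {
    a1 <- ds$calls[keep, l, 1]; a2 <- ds$calls[keep, l, 2]
    ok <- !is.na(a1)
    nmat[, l] <- as.integer(table(popf[ok]))
    states <- sort(unique(c(a1[ok], a2[ok])))
    if (!length(states)) {
      freq[[l]] <- matrix(0, length(pops), 0, dimnames = list(pops, NULL))
      next
    }
    cnt <- table(factor(rep(popf[ok], 2L), levels = pops),
                 factor(c(a1[ok], a2[ok]), levels = states))
    cnt <- matrix(as.numeric(cnt), nrow = length(pops),
                  dimnames = list(pops, as.character(states)))
    tot <- rowSums(cnt)
    f <- cnt / ifelse(tot > 0, tot, 1)
    freq[[l]] <- f
  }
  structure(list(pops = pops, loci = ds$loci, n = nmat, freq = freq),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d populations x %d loci\n",
              length(x$pops), length(x$loci)))
  invisible(x)
}

#' Standardize sample sizes by subsampling
#'
#' Draws exactly \code{n_per_pop} individuals from every population without
#' replacement, so diversity statistics are compared at equal sample size.
#'
#' @param ds a [genotype_dataset()].
#' @param n_per_pop target number of individuals per population.
#' @param seed integer seed; the draw is deterministic given it.
#' @return a [genotype_dataset()] with \code{n_per_pop} individuals per
#'   population, in original relative order.
#' @export
standardize_sample <- function(ds, n_per_pop, seed = 1L) {
  sizes <- table(ds$populations)
  small <- names(sizes)[sizes < n_per_pop]
  if (length(small))
    stop("population(s) smaller than n_per_pop = ", n_per_pop, ": ",
         paste(small, collapse = ", "))
  keep <- with_seed(seed, {
    unlist(lapply(pop_levels(ds), function(p) {
      rows <- which(ds$populations == p)
      sort(sample(rows, n_per_pop))
    }))
  })
  subset_individuals(ds, keep)
}
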