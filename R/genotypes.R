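#' Diploid microsatellite genotype dataset
#'
#' The central data container of the package: diploid allele-size calls
#' (in base pairs) for a set of individuals scored at a panel of SSR loci,
#' with a population label per individual. Missing data are only accepted
#' as a whole missing genotype (both alleles `NA` at a locus); a genotype
#' with exactly one missing allele is rejected, matching SSR scoring
#' practice where a locus either amplifies or it does not.
#'
#' @param alleles integer matrix with one row per individual and
#'   `2 * nrow(loci)` columns; columns `2j - 1` and `2j` hold the two
#'   allele sizes at locus `j`. `NA` marks missing.
#' @param pop character or factor of population IDs, one per individual.
#' @param ind character vector of individual IDs (default `ind_1 ...`).
#' @param loci data.frame with columns `name` and `motif` (repeat motif
#'   length in base pairs).
#' @param populations optional character vector fixing population order;
#'   defaults to order of first appearance.
#' @param raw logical; if `TRUE` the allele-ladder check (all alleles at a
#'   locus congruent modulo the motif length) is skipped.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(alleles, pop, ind = NULL, loci = NULL,
                             populations = NULL, raw = FALSE) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n <- nrow(alleles)
  if (ncol(alleles) %% 2L != 0L)
    stop("allele matrix must have an even number of columns (two per locus)")
  nloc <- ncol(alleles) %/% 2L
  if (is.null(loci))
    loci <- data.frame(name = paste0("L", seq_len(nloc)), motif = 2L)
  loci$name <- as.character(loci$name)
  loci$motif <- as.integer(loci$motif)
  if (nrow(loci) != nloc)
    stop("loci table has ", nrow(loci), " rows but alleles imply ", nloc, " loci")
  if (length(pop) != n)
    stop("pop has length ", length(pop), ", expected ", n)
  pop <- as.character(pop)
  if (is.null(populations)) populations <- unique(pop)
  if (!all(pop %in% populations))
    stop("individual population IDs missing from the population list")
  if (is.null(ind)) ind <- paste0("ind_", seq_len(n))

  a1 <- alleles[, seq(1L, 2L * nloc, by = 2L), drop = FALSE]
  a2 <- alleles[, seq(2L, 2L * nloc, by = 2L), drop = FALSE]
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("single-allele missingness at ", sum(half),
         " genotype(s); a missing genotype must drop both alleles")
  if (any(alleles <= 0L, na.rm = TRUE))
    stop("allele sizes must be positive integers")
  if (!raw) {
    for (j in seq_len(nloc)) {
      sz <- c(a1[, j], a2[, j])
      sz <- sz[!is.na(sz)]
      if (length(sz) > 1L && any((sz - min(sz)) %% loci$motif[j] != 0L))
        stop("alleles at locus ", loci$name[j],
             " are not on a ladder of motif length ", loci$motif[j],
             " (use raw = TRUE to skip this check)")
    }
  }
  structure(
    list(alleles = alleles, pop = pop, ind = as.character(ind),
         loci = loci, populations = populations, raw = raw),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$ind), "individuals,",
      length(x$populations), "populations,", nrow(x$loci), "loci\n")
  miss <- mean(is.na(x$alleles))
  cat(sprintf("  missing allele calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of loci / individuals / populations
#' @param ds a `genotype_dataset`.
#' @return integer count.
#' @export
n_loci <- function(ds) nrow(ds$loci)

#' @rdname n_loci
#' @export
n_individuals <- function(ds) length(ds$ind)

#' @rdname n_loci
#' @export
n_populations <- function(ds) length(ds$populations)

# both allele columns for locus j
locus_cols <- function(j) c(2L * j - 1L, 2L * j)

#' Extract the two allele columns of one locus
#'
#' @param ds a `genotype_dataset`.
#' @param locus locus name or index.
#' @return integer matrix with columns `a1`, `a2` (one row per individual).
#' @export
locus_alleles <- function(ds, locus) {
  j <- locus_index(ds, locus)
  m <- ds$alleles[, locus_cols(j), drop = FALSE]
  colnames(m) <- c("a1", "a2")
  m
}

locus_index <- function(ds, locus) {
  if (is.numeric(locus)) {
    j <- as.integer(locus)
    if (j < 1L || j > n_loci(ds)) stop("locus index out of range: ", locus)
    return(j)
  }
  j <- match(locus, ds$loci$name)
  if (is.na(j)) stop("unknown locus: ", locus)
  j
}

#' Allele gene-copy counts at a locus
#'
#' @param ds a `genotype_dataset`.
#' @param locus locus name or index.
#' @param by_pop if `TRUE`, return a matrix of counts (rows = alleles,
#'   columns = populations); otherwise a named vector pooled over
#'   populations.
#' @return table of gene-copy counts, allele sizes as dimnames.
#' @export
allele_counts <- function(ds, locus, by_pop = FALSE) {
  m <- locus_alleles(ds, locus)
  sizes <- c(m[, 1L], m[, 2L])
  keep <- !is.na(sizes)
  if (!by_pop) {
    tab <- table(factor(sizes[keep]))
    out <- as.integer(tab)
    names(out) <- names(tab)
    return(out)
  }
  popv <- rep(ds$pop, 2L)[keep]
  tab <- table(factor(sizes[keep]),
               factor(popv, levels = ds$populations))
  cnt <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  cnt
}

#' Restrict a dataset to a subset of populations
#'
#' @param ds a `genotype_dataset`.
#' @param pops character vector of population IDs to keep.
#' @return a `genotype_dataset` containing only those populations.
#' @export
subset_populations <- function(ds, pops) {
  if (!all(pops %in% ds$populations))
    stop("unknown population(s): ",
         paste(setdiff(pops, ds$populations), collapse = ", "))
  keep <- ds$pop %in% pops
  genotype_dataset(ds$alleles[keep, , drop = FALSE], ds$pop[keep],
                   ds$ind[keep], ds$loci, populations = pops, raw = ds$raw)
}

#' Merge populations into pools
#'
#' Relabels populations according to a pool assignment; used to collapse a
#' many-population dataset into the gene pools an ABC analysis compares.
#'
#' @param ds a `genotype_dataset`.
#' @param pools named character vector or list mapping population ID to
#'   pool ID. Populations absent from the map are dropped.
#' @return a `genotype_dataset` whose populations are the pools.
#' @export
pool_populations <- function(ds, pools) {
  pools <- unlist(pools)
  keep <- ds$pop %in% names(pools)
  newpop <- unname(pools[ds$pop[keep]])
  genotype_dataset(ds$alleles[keep, , drop = FALSE], newpop, ds$ind[keep],
                   ds$loci, populations = unique(unname(pools)), raw = ds$raw)
}

#' Compare two genotype datasets for equality
#'
#' @param a,b `genotype_dataset` objects.
#' @return `TRUE` if loci, populations, individuals and allele calls agree.
#' @export
datasets_equal <- function(a, b) {
  isTRUE(all.equal(a$loci$name, b$loci$name)) &&
    isTRUE(all.equal(a$loci$motif, b$loci$motif)) &&
    identical(a$populations, b$populations) &&
    identical(a$pop, b$pop) &&
    identical(unname(a$alleles), unname(b$alleles))
}
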