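#' Two-phase mutation model for bottleneck tests
#'
#' Mixture of single-step mutations (proportion `prop_smm`) and multistep
#' mutations whose magnitudes follow a geometric distribution
#' parameterized by its variance.
#'
#' @param prop_smm proportion of strict single-step mutations
#'   (default 0.70).
#' @param variance variance of the multistep geometric magnitude
#'   (default 30).
#' @return object of class `tpm_model`, usable as a step sampler.
#' @export
mutation_model_tpm <- function(prop_smm = 0.70, variance = 30) {
  stopifnot(prop_smm >= 0, prop_smm <= 1, variance > 0)
  # geometric on {1, 2, ...} with success prob q: variance (1-q)/q^2
  q <- (-1 + sqrt(1 + 4 * variance)) / (2 * variance)
  structure(list(prop_smm = prop_smm, variance = variance, q = q),
            class = "tpm_model")
}

tpm_step_sampler <- function(model) {
  force(model)
  function(nmut) {
    if (nmut == 0L) return(integer(0))
    multi <- stats::runif(nmut) > model$prop_smm
    mag <- rep(1L, nmut)
    if (any(multi))
      mag[multi] <- 1L + stats::rgeom(sum(multi), prob = model$q)
    mag * sample(c(-1L, 1L), nmut, replace = TRUE)
  }
}

# unbiased expected heterozygosity from gene-copy allele sizes
unbiased_het <- function(sizes) {
  n <- length(sizes)
  p <- as.numeric(table(sizes)) / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Equilibrium heterozygosity distribution conditional on allele count
#'
#' Coalescent simulations of `n` gene copies under the mutation model,
#' with theta calibrated by stochastic bisection so the expected allele
#' count matches `k`, then rejection-retained until `nreps` runs carry
#' exactly `k` alleles. The unbiased expected heterozygosity of each
#' retained run forms the equilibrium (Heq) distribution against which an
#' observed heterozygosity is standardized.
#'
#' @param k observed allele count to condition on (2 <= k <= n).
#' @param n gene copies.
#' @param model a [mutation_model_tpm()].
#' @param nreps retained replicates (default 10000).
#' @param seed optional seed.
#' @param calib_reps simulations per bisection step.
#' @return numeric vector of `nreps` Heq values, with the calibrated
#'   theta as attribute `theta`.
#' @export
equilibrium_het_distribution <- function(k, n, model = mutation_model_tpm(),
                                         nreps = 10000L, seed = NULL,
                                         calib_reps = 300L) {
  if (!is.null(seed)) set.seed(seed)
  if (k < 2L || k > n) stop("need 2 <= k <= n")
  stepper <- tpm_step_sampler(model)
  mean_k <- function(theta, reps) {
    mean(vapply(seq_len(reps), function(i)
      length(unique(sim_single_pop(n, theta, stepper))), numeric(1)))
  }
  lo <- 1e-3; hi <- 4096
  for (it in seq_len(14L)) {
    mid <- sqrt(lo * hi)
    if (mean_k(mid, calib_reps) < k) lo <- mid else hi <- mid
  }
  theta <- sqrt(lo * hi)
  out <- numeric(nreps); got <- 0L
  attempts <- 0L; max_attempts <- 400L * nreps
  while (got < nreps) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not collect runs with exactly k = ", k,
           " alleles; k may be unattainable at n = ", n)
    sz <- sim_single_pop(n, theta, stepper)
    if (length(unique(sz)) == k) {
      got <- got + 1L
      out[got] <- unbiased_het(sz)
    }
  }
  attr(out, "theta") <- theta
  out
}

#' Heterozygosity-excess bottleneck test
#'
#' For each polymorphic locus the observed unbiased heterozygosity is
#' standardized against the simulated equilibrium distribution
#' conditional on the observed allele count; a one-tailed Wilcoxon
#' signed-rank test (exact for 25 or fewer loci) asks whether loci show a
#' systematic heterozygosity excess, the signature of a recent reduction
#' in effective size.
#'
#' @param dataset a [genotype_dataset()].
#' @param population population ID.
#' @param model a [mutation_model_tpm()].
#' @param nreps equilibrium replicates per locus.
#' @param seed optional seed.
#' @param heq_cache optional environment used to memoise the (k, n)
#'   equilibrium distributions across calls.
#' @return list with `per_locus` data.frame (`locus`, `k`, `n_copies`,
#'   `He`, `Heq_mean`, `Heq_sd`, `std_diff`), and `p_excess` from the
#'   Wilcoxon signed-rank test.
#' @export
het_excess_test <- function(dataset, population,
                            model = mutation_model_tpm(),
                            nreps = 10000L, seed = NULL,
                            heq_cache = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sub <- subset_populations(dataset, population)
  rows <- list()
  for (j in seq_len(n_loci(sub))) {
    m <- locus_alleles(sub, j)
    keep <- !is.na(m[, 1L])
    sizes <- c(m[keep, 1L], m[keep, 2L])
    k <- length(unique(sizes))
    if (k < 2L) next
    n <- length(sizes)
    key <- paste0("k", k, "_n", n)
    heq <- if (!is.null(heq_cache) && !is.null(heq_cache[[key]]))
      heq_cache[[key]]
    else {
      h <- equilibrium_het_distribution(k, n, model, nreps = nreps)
      if (!is.null(heq_cache)) heq_cache[[key]] <- h
      h
    }
    he <- unbiased_het(sizes)
    rows[[length(rows) + 1L]] <- data.frame(
      locus = sub$loci$name[j], k = k, n_copies = n, He = he,
      Heq_mean = mean(heq), Heq_median = stats::median(heq),
      Heq_sd = stats::sd(heq),
      std_diff = (he - mean(heq)) / stats::sd(heq))
  }
  per <- do.call(rbind, rows)
  if (is.null(per) || nrow(per) < 4L)
    stop("heterozygosity-excess test needs at least 4 polymorphic loci")
  # the conditional Heq distribution is left-skewed, so differences from
  # its mean are positive more than half the time even at equilibrium;
  # centring the signed-rank test on the conditional median keeps its
  # size at the nominal level (the reported standardized differences
  # stay mean-based)
  diffs <- per$He - per$Heq_median
  list(per_locus = per, p_excess = wilcoxon_excess_p(diffs))
}

# one-tailed (excess) signed-rank p-value; exact for <= 25 untied values
wilcoxon_excess_p <- function(diffs) {
  ok_exact <- length(diffs) <= 25L && !any(diffs == 0) &&
    !anyDuplicated(abs(diffs))
  stats::wilcox.test(diffs, alternative = "greater",
                     exact = ok_exact)$p.value
}

#' Mode-shift (shifted allele distribution) test
#'
#' Pools allele frequencies within the population into ten classes of
#' width 0.1. Populations near mutation-drift equilibrium show an
#' L-shaped distribution (the rarest class holds the most alleles); a
#' shifted mode suggests a bottleneck. Ties with the first class are
#' classified as shifted.
#'
#' @param dataset a [genotype_dataset()].
#' @param population population ID.
#' @return list with `class` (`"L-shaped"` or `"shifted"`) and `bins`
#'   (allele counts per frequency class).
#' @export
mode_shift <- function(dataset, population) {
  sub <- subset_populations(dataset, population)
  freqs <- numeric(0)
  for (j in seq_len(n_loci(sub))) {
    cnt <- allele_counts(sub, j)
    if (length(cnt) < 2L) next
    freqs <- c(freqs, cnt / sum(cnt))
  }
  if (length(freqs) == 0L) stop("no polymorphic locus in ", population)
  bins <- table(cut(freqs, breaks = seq(0, 1, by = 0.1),
                    include.lowest = TRUE))
  cls <- if (bins[1L] > max(bins[-1L])) "L-shaped" else "shifted"
  list(class = cls, bins = bins)
}

#' Garza-Williamson M-ratio
#'
#' Per locus, M = k / (r + 1) with k the allele count and r the allele
#' size range in repeat units; M well below the 0.68 critical threshold
#' signals an old or severe bottleneck (lost alleles leave gaps in the
#' ladder faster than the range contracts).
#'
#' @param dataset a [genotype_dataset()].
#' @param population population ID.
#' @param threshold critical value for the flag (default 0.68).
#' @return list with `per_locus` data.frame (`locus`, `k`, `range`, `M`),
#'   `mean_M` over defined loci, and `below_threshold`.
#' @export
m_ratio <- function(dataset, population, threshold = 0.68) {
  sub <- subset_populations(dataset, population)
  nloc <- n_loci(sub)
  out <- data.frame(locus = sub$loci$name, k = NA_integer_,
                    range = NA_integer_, M = NA_real_)
  for (j in seq_len(nloc)) {
    cnt <- allele_counts(sub, j)
    if (length(cnt) < 2L) next
    sizes <- as.integer(names(cnt))
    motif <- sub$loci$motif[j]
    span <- max(sizes) - min(sizes)
    if (span %% motif != 0L)
      stop("allele sizes at locus ", sub$loci$name[j],
           " are not multiples of the motif length ", motif)
    r <- span %/% motif
    out$k[j] <- length(cnt)
    out$range[j] <- r
    out$M[j] <- length(cnt) / (r + 1)
  }
  mm <- mean(out$M, na.rm = TRUE)
  list(per_locus = out, mean_M = mm,
       below_threshold = is.finite(mm) && mm < threshold)
}
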