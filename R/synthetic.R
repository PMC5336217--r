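#' Island-model configuration
#'
#' Symmetric finite-island model: equal-size demes exchanging migrants at
#' a common rate, simulated with the same coalescent kernel as the
#' demographic scenarios (internal deme size N = 1000 diploids; the
#' mutation and migration rates are derived from the scaled parameters).
#'
#' @param n_pops number of demes.
#' @param n_per_pop diploid sample size per deme.
#' @param n_loci number of loci.
#' @param theta scaled mutation rate 4 N mu per locus (> 0).
#' @param migration scaled migration rate 4 N m (per-lineage emigration
#'   probability scaled by 4N); 0 means isolated demes.
#' @param P GSM geometric parameter in [0, 1).
#' @param motif repeat motif length (bp).
#' @param seed RNG seed.
#' @return object of class `island_config`.
#' @export
island_config <- function(n_pops, n_per_pop, n_loci = 14L, theta = 2,
                          migration = 10, P = 0.22, motif = 2L,
                          seed = 1L) {
  stopifnot(theta > 0, P >= 0, P < 1, n_pops >= 1, n_per_pop >= 1,
            migration >= 0)
  structure(list(n_pops = as.integer(n_pops),
                 n_per_pop = as.integer(n_per_pop),
                 n_loci = as.integer(n_loci), theta = theta,
                 migration = migration, P = P, motif = as.integer(motif),
                 seed = as.integer(seed)),
            class = "island_config")
}

#' Generate a genotype dataset under the island model
#'
#' @param config an [island_config()].
#' @return a [genotype_dataset()] with `n_pops` populations.
#' @export
generate_island_dataset <- function(config) {
  set.seed(config$seed)
  N <- 1000
  mu <- config$theta / (4 * N)
  m <- config$migration / (4 * N)
  pools <- paste0("pop_", seq_len(config$n_pops))
  if (config$n_pops > 1L && config$migration <= 0)
    stop("isolated demes never share an ancestor; use the scenario ",
         "simulator for divergence models")
  samples <- stats::setNames(rep(2L * config$n_per_pop, config$n_pops),
                             pools)
  pool_sizes <- stats::setNames(rep(N, config$n_pops), pools)
  n_ind <- config$n_pops * config$n_per_pop
  alleles <- matrix(NA_integer_, n_ind, 2L * config$n_loci)
  for (j in seq_len(config$n_loci)) {
    loc <- sim_locus(samples, pool_sizes, events = list(), mu = mu,
                     p_geom = config$P, migration = m)
    bp <- as.integer(loc$sizes) * config$motif
    alleles[, 2L * j - 1L] <- bp[seq(1L, length(bp), 2L)]
    alleles[, 2L * j] <- bp[seq(2L, length(bp), 2L)]
  }
  loci <- data.frame(name = paste0("L", seq_len(config$n_loci)),
                     motif = config$motif)
  genotype_dataset(alleles, rep(pools, each = config$n_per_pop),
                   loci = loci, populations = pools)
}

#' Generate one dataset under a demographic scenario
#'
#' Thin entry point over [simulate_dataset()] that validates the scenario
#' and the parameter vector first.
#'
#' @param spec a [scenario_spec()].
#' @param params named parameter vector (must satisfy the scenario's
#'   ordering constraints; must include `mu` and `P` or a `locus_model`
#'   to draw them from).
#' @param plan named diploid sampling plan.
#' @param locus_model a [locus_model()].
#' @param seed integer seed.
#' @return a [genotype_dataset()].
#' @export
generate_from_scenario <- function(spec, params, plan, locus_model,
                                   seed = 1L) {
  validate_scenario(spec)
  simulate_dataset(spec, params, plan, locus_model, seed = seed)
}

#' Inject null alleles at one locus
#'
#' Each gene copy independently becomes a null (non-amplifying) allele
#' with probability `null_freq`; a visible/null heterozygote is scored as
#' a visible homozygote and a null/null genotype as missing — the
#' classical null-allele artefact under Hardy-Weinberg pairing.
#'
#' @param dataset a [genotype_dataset()].
#' @param locus locus name or index.
#' @param null_freq null-allele frequency in [0, 0.5].
#' @param seed integer seed.
#' @return modified [genotype_dataset()].
#' @export
inject_null_alleles <- function(dataset, locus, null_freq, seed = 1L) {
  if (null_freq < 0 || null_freq > 0.5)
    stop("null_freq must lie in [0, 0.5]")
  if (null_freq == 0) return(dataset)
  set.seed(seed)
  j <- locus_index(dataset, locus)
  cols <- locus_cols(j)
  m <- dataset$alleles[, cols]
  n <- nrow(m)
  null1 <- stats::runif(n) < null_freq
  null2 <- stats::runif(n) < null_freq
  both <- null1 & null2
  one1 <- null1 & !null2
  one2 <- null2 & !null1
  m[one1, 1L] <- m[one1, 2L]   # only the visible allele amplifies
  m[one2, 2L] <- m[one2, 1L]
  m[both, ] <- NA_integer_
  dataset$alleles[, cols] <- m
  dataset
}

#' Study-shaped synthetic fixture
#'
#' A synthetic stand-in for the Eurasian walnut collection: 91
#' populations of about 22 diploid trees (2,008 in total) scored at 14
#' SSR loci (~200 alleles in total), placed on a Eurasian-like
#' coordinate span with a built-in west-to-east gradient in diversity
#' (eastern populations draw from richer allele pools), emulating the
#' longitudinal allelic-richness cline of the study system. Genotypes
#' are Hardy-Weinberg draws from per-population frequencies; no
#' coalescent history is implied.
#'
#' @param seed integer seed.
#' @return list with `dataset` (a [genotype_dataset()]) and `metadata`
#'   (data.frame `id`, `lat`, `lon`, `elev`, `n`).
#' @export
study_shape_fixture <- function(seed = 1L) {
  set.seed(seed)
  n_pops <- 91L; n_loci <- 14L; total_ind <- 2008L
  pops <- sprintf("P%02d", seq_len(n_pops))
  base <- 8L
  extra <- stats::rmultinom(1L, total_ind - n_pops * base,
                            rep(1 / n_pops, n_pops))[, 1L]
  sizes <- base + extra
  lon <- sort(stats::runif(n_pops, -5, 90))
  lat <- stats::runif(n_pops, 35, 52)
  elev <- round(stats::runif(n_pops, 50, 2500))
  # per-locus global allele ladders; ~200 alleles in total
  n_alleles <- 2L + stats::rpois(n_loci, 12)
  grad <- (lon - min(lon)) / diff(range(lon))  # 0 (west) .. 1 (east)
  conc <- 1.5 + 28.5 * grad  # Dirichlet concentration scales diversity
  alleles <- matrix(NA_integer_, total_ind, 2L * n_loci)
  pop_of_ind <- rep(pops, times = sizes)
  for (j in seq_len(n_loci)) {
    K <- n_alleles[j]
    sz <- (100L + seq_len(K) - 1L) * 2L  # dinucleotide ladder in bp
    # broken-stick global frequencies
    gfreq <- sort(stats::rexp(K), decreasing = TRUE)
    gfreq <- gfreq / sum(gfreq)
    row0 <- 0L
    for (i in seq_len(n_pops)) {
      a <- stats::rgamma(K, shape = conc[i] * gfreq)
      if (sum(a) == 0) a[which.max(gfreq)] <- 1
      pfreq <- a / sum(a)
      g <- sample.int(K, 2L * sizes[i], replace = TRUE, prob = pfreq)
      gi <- matrix(sz[g], ncol = 2L)
      alleles[row0 + seq_len(sizes[i]), locus_cols(j)] <- gi
      row0 <- row0 + sizes[i]
    }
  }
  loci <- data.frame(name = paste0("WGA", seq_len(n_loci)), motif = 2L)
  ds <- genotype_dataset(alleles, pop_of_ind, loci = loci,
                         populations = pops)
  meta <- data.frame(id = pops, lat = lat, lon = lon, elev = elev,
                     n = sizes)
  list(dataset = ds, metadata = meta)
}

#' Deliberately well-separated toy scenarios
#'
#' Three two-pool scenarios used for scenario-recovery experiments:
#' long isolation (high differentiation, balanced diversity), recent
#' split (nearly panmictic), and isolation with a crashed second pool
#' (strong drift and low diversity in pool2). Sample plan: 20 diploids
#' per pool.
#'
#' @return named list of three validated [scenario_spec()] objects.
#' @export
toy_scenarios <- function() {
  mk <- function(name, desc, priors, t_ev = "t_split",
                 extra_events = list()) {
    ev <- c(extra_events,
            list(list(type = "merge", time = t_ev, source = "pool2",
                      sink = "pool1")))
    spec <- scenario_spec(
      name,
      data.frame(id = c("pool1", "pool2"), size = c("N1", "N2"),
                 stringsAsFactors = FALSE),
      ev, priors, character(0), desc)
    validate_scenario(spec)
    spec
  }
  isolation <- mk(
    "isolation",
    "old split, equal sizes: high FST, balanced diversity",
    list(N1 = list(dist = "uniform", min = 2000, max = 10000),
         N2 = list(dist = "uniform", min = 2000, max = 10000),
         t_split = list(dist = "uniform", min = 1000, max = 4000)))
  recent <- mk(
    "recent_split",
    "very recent split of a large population: FST near zero",
    list(N1 = list(dist = "uniform", min = 2000, max = 10000),
         N2 = list(dist = "uniform", min = 2000, max = 10000),
         t_split = list(dist = "uniform", min = 5, max = 20)))
  crash <- mk(
    "bottleneck",
    "old split with pool2 held at a tiny size: low diversity in pool2",
    list(N1 = list(dist = "uniform", min = 2000, max = 10000),
         N2 = list(dist = "uniform", min = 30, max = 300),
         t_split = list(dist = "uniform", min = 1000, max = 4000)))
  list(isolation = isolation, recent_split = recent, bottleneck = crash)
}
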