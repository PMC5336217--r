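#' @name validation-experiments
#' @title Built-in confidence and calibration experiments
#'
#' @description
#' The genotype data behind the walnut analyses are not redistributable,
#' so the pipeline's operating characteristics are validated by
#' simulation instead: scenario-choice recovery on deliberately
#' well-separated toy scenarios, parameter recovery under a known truth,
#' simulator-against-theory checks of the GSM coalescent, and the type-I
#' behaviour of the bottleneck heterozygosity-excess test at mutation-
#' drift equilibrium. Each experiment runs end-to-end through the same
#' public functions the real analyses use.
NULL

#' Two-pool divergence scenario used for parameter recovery
#'
#' Both pools and the ancestor share one effective size N; pool2 splits
#' from pool1 at `t_split`. With the mutation rate pinned, N and
#' `t_split` are both identifiable, which is what a recovery experiment
#' needs.
#'
#' @return a validated [scenario_spec()].
#' @export
recovery_scenario <- function() {
  spec <- scenario_spec(
    "recovery",
    data.frame(id = c("pool1", "pool2"), size = c("N", "N"),
               stringsAsFactors = FALSE),
    list(list(type = "merge", time = "t_split", source = "pool2",
              sink = "pool1")),
    list(N = list(dist = "uniform", min = 100, max = 10000),
         t_split = list(dist = "uniform", min = 10, max = 500)))
  validate_scenario(spec)
  spec
}

#' Scenario-recovery experiment
#'
#' Builds a reference table over the three toy scenarios
#' ([toy_scenarios()]), simulates pseudo-observed datasets with
#' prior-drawn parameters under each scenario in turn, and records how
#' often the generating scenario attains the top logistic-regression
#' posterior probability.
#'
#' @param n_per_scenario reference-table rows per scenario (default 500).
#' @param n_pods pseudo-observed datasets (default 50).
#' @param fraction retained proportion for the model choice.
#' @param plan diploid sampling plan (default 20 per pool).
#' @param n_loci loci per dataset (default 14).
#' @param seed master seed.
#' @return list with `rate`, `n_pods`, `winners`, `generating`.
#' @export
scenario_recovery_experiment <- function(n_per_scenario = 500L,
                                         n_pods = 50L, fraction = 0.1,
                                         plan = c(pool1 = 20L,
                                                  pool2 = 20L),
                                         n_loci = 14L, seed = 1L) {
  scns <- toy_scenarios()
  lm <- locus_model(n_loci = n_loci)
  tab <- build_reference_table(scns, n_per_scenario, plan, lm,
                               seed = seed)
  set.seed(seed + 1L)
  pod_seeds <- sample.int(.Machine$integer.max - 1L, n_pods)
  generating <- rep(names(scns), length.out = n_pods)
  winners <- character(n_pods)
  for (i in seq_len(n_pods)) {
    set.seed(pod_seeds[i])
    spec <- scns[[generating[i]]]
    params <- draw_parameters(spec, lm)
    pod <- simulate_dataset(spec, params, plan, lm)
    winners[i] <- top_scenario(tab, summary_statistics(pod), fraction)
  }
  list(rate = mean(winners == generating), n_pods = n_pods,
       winners = winners, generating = generating)
}

#' Parameter-recovery experiment
#'
#' Simulates pseudo-observed datasets under the [recovery_scenario()]
#' at a known truth (N = 2000, t_split = 50 by default), estimates the
#' posterior for each through rejection plus local-linear adjustment,
#' and scores a replicate as recovered when every checked posterior
#' median lies within a factor of two of the truth. The mutation model
#' is pinned to the true rate so that sizes and times are identifiable.
#'
#' @param n_table reference-table rows (default 1500).
#' @param n_pods replicates (default 50).
#' @param fraction retained proportion (default 0.1).
#' @param truth named truth vector (`N`, `t_split`).
#' @param plan diploid sampling plan (default 30 per pool).
#' @param seed master seed.
#' @return list with `rate`, per-replicate medians, and the truth.
#' @export
parameter_recovery_experiment <- function(n_table = 1500L, n_pods = 50L,
                                          fraction = 0.1,
                                          truth = c(N = 2000,
                                                    t_split = 50),
                                          plan = c(pool1 = 30L,
                                                   pool2 = 30L),
                                          seed = 1L) {
  rec <- recovery_scenario()
  lm_fix <- locus_model(n_loci = 14L, mu_min = 4.99e-4,
                        mu_max = 5.01e-4, p_min = 0.199, p_max = 0.201)
  tab <- build_reference_table(list(recovery = rec), n_table, plan,
                               lm_fix, seed = seed)
  set.seed(seed + 1L)
  pod_seeds <- sample.int(.Machine$integer.max - 1L, n_pods)
  full_truth <- c(truth, mu = 5e-4, P = 0.2)
  med <- matrix(NA_real_, n_pods, length(truth),
                dimnames = list(NULL, names(truth)))
  for (i in seq_len(n_pods)) {
    pod <- simulate_dataset(rec, full_truth, plan, lm_fix,
                            seed = pod_seeds[i])
    est <- suppressWarnings(
      estimate_parameters(tab, summary_statistics(pod), fraction,
                          "recovery"))
    med[i, ] <- est$median[match(names(truth), est$param)]
  }
  ok <- sweep(med, 2L, truth, "/")
  recovered <- apply(ok >= 0.5 & ok <= 2, 1L, all)
  list(rate = mean(recovered), medians = med, truth = truth,
       recovered = recovered)
}

#' Simulator-against-theory check
#'
#' For two gene copies in one constant pool the expected squared
#' allele-size difference under the GSM is theta (1 + P) / (1 - P)^2;
#' the experiment simulates replicate loci at several (theta, P)
#' settings and reports the Monte-Carlo deviation in standard errors.
#'
#' @param theta_values scaled mutation rates to test.
#' @param P_values GSM parameters to test.
#' @param n_reps replicate loci per setting (default 2000).
#' @param seed seed.
#' @return data.frame `theta`, `P`, `expected`, `observed`, `se`,
#'   `z` (deviation in SEs).
#' @export
simulator_theory_check <- function(theta_values = c(1, 2, 5),
                                   P_values = c(0, 0.2),
                                   n_reps = 2000L, seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(theta = theta_values, P = P_values)
  grid$expected <- grid$theta * (1 + grid$P) / (1 - grid$P)^2
  grid$observed <- grid$se <- NA_real_
  N <- 1000
  for (i in seq_len(nrow(grid))) {
    mu <- grid$theta[i] / (4 * N)
    d2 <- vapply(seq_len(n_reps), function(r) {
      s <- sim_locus(c(a = 2L), c(a = N), list(), mu = mu,
                     p_geom = grid$P[i])
      diff(s$sizes)^2
    }, numeric(1))
    grid$observed[i] <- mean(d2)
    grid$se[i] <- stats::sd(d2) / sqrt(n_reps)
  }
  grid$z <- (grid$observed - grid$expected) / grid$se
  grid
}

#' Type-I error of the heterozygosity-excess test at equilibrium
#'
#' Simulates populations at mutation-drift equilibrium under the TPM,
#' applies the heterozygosity-excess bottleneck test to each, and
#' reports the rejection rate at the 5% level, which should sit near
#' the nominal level. Equilibrium (k, n) reference distributions are
#' memoised across fixtures.
#'
#' @param n_fixtures simulated equilibrium populations (default 200).
#' @param n_loci loci per fixture (default 10).
#' @param n_diploid diploid individuals per fixture (default 25).
#' @param theta scaled mutation rate of the equilibrium fixtures.
#' @param nreps retained equilibrium replicates per (k, n).
#' @param seed master seed.
#' @return list with `rate`, `p_values`, `n_fixtures`.
#' @export
bottleneck_type1_experiment <- function(n_fixtures = 200L, n_loci = 10L,
                                        n_diploid = 25L, theta = 5,
                                        nreps = 800L, seed = 1L) {
  model <- mutation_model_tpm()
  stepper <- tpm_step_sampler(model)
  cache <- new.env(parent = emptyenv())
  set.seed(seed)
  fixture_seeds <- sample.int(.Machine$integer.max - 1L, n_fixtures)
  pvals <- rep(NA_real_, n_fixtures)
  for (f in seq_len(n_fixtures)) {
    set.seed(fixture_seeds[f])
    alleles <- matrix(NA_integer_, n_diploid, 2L * n_loci)
    for (j in seq_len(n_loci)) {
      sz <- 2L * sim_single_pop(2L * n_diploid, theta, stepper)
      alleles[, 2L * j - 1L] <- sz[seq_len(n_diploid)]
      alleles[, 2L * j] <- sz[n_diploid + seq_len(n_diploid)]
    }
    ds <- genotype_dataset(
      alleles, rep("pop", n_diploid),
      loci = data.frame(name = paste0("L", seq_len(n_loci)), motif = 2L))
    res <- tryCatch(
      het_excess_test(ds, "pop", model, nreps = nreps, seed = f,
                      heq_cache = cache),
      error = function(e) NULL)
    if (!is.null(res)) pvals[f] <- res$p_excess
  }
  ok <- !is.na(pvals)
  list(rate = mean(pvals[ok] < 0.05), p_values = pvals,
       n_fixtures = sum(ok))
}

#' Equilibrium behaviour of the M-ratio
#'
#' Simulates stationary populations under strict stepwise mutation and
#' reports how often the mean M-ratio stays above the bottleneck
#' threshold.
#'
#' @param n_fixtures replicates (default 200).
#' @param n_loci loci per fixture (default 8).
#' @param n_copies gene copies per locus (default 50).
#' @param theta scaled mutation rate (default 5).
#' @param threshold critical value (default 0.68).
#' @param seed seed.
#' @return list with `rate_above`, `mean_M` per fixture.
#' @export
m_ratio_equilibrium_experiment <- function(n_fixtures = 200L,
                                           n_loci = 8L, n_copies = 50L,
                                           theta = 5, threshold = 0.68,
                                           seed = 1L) {
  set.seed(seed)
  stepper <- make_gsm_sampler(0)
  meanM <- vapply(seq_len(n_fixtures), function(r) {
    mean(vapply(seq_len(n_loci), function(j) {
      sz <- sim_single_pop(n_copies, theta, stepper)
      k <- length(unique(sz))
      if (k < 2L) return(NA_real_)
      k / (diff(range(sz)) + 1)
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  list(rate_above = mean(meanM > threshold), mean_M = meanM)
}
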