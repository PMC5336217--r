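#' Build an ABC reference table
#'
#' Simulates `n_per_scenario` datasets per scenario (parameters drawn
#' from the priors), computes the summary-statistic vector of each, and
#' stores per-statistic median-absolute-deviation normalization
#' constants. Every row uses its own RNG substream derived from the
#' master seed by row counter, so the table is identical whatever order
#' rows are evaluated in.
#'
#' @param scenarios named list of validated [scenario_spec()] objects.
#' @param n_per_scenario simulated datasets per scenario.
#' @param plan named diploid sampling plan (pool -> individuals).
#' @param locus_model a [locus_model()].
#' @param seed master seed.
#' @param row_order optional permutation of row indices fixing the
#'   evaluation order (the result is identical for any permutation;
#'   exposed to demonstrate that).
#' @return object of class `reference_table`: `stats` matrix, `scenario`
#'   factor, `params` list of named vectors, `mad` normalization vector,
#'   plus the inputs.
#' @export
build_reference_table <- function(scenarios, n_per_scenario, plan,
                                  locus_model, seed, row_order = NULL) {
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, function(s) s$name, character(1))
  nsc <- length(scenarios)
  total <- nsc * n_per_scenario
  set.seed(seed)
  row_seeds <- sample.int(.Machine$integer.max - 1L, total)
  scen_of_row <- rep(names(scenarios), each = n_per_scenario)
  order_idx <- if (is.null(row_order)) seq_len(total) else row_order
  stopifnot(sort(order_idx) == seq_len(total))
  stats_list <- vector("list", total)
  params_list <- vector("list", total)
  for (r in order_idx) {
    set.seed(row_seeds[r])
    spec <- scenarios[[scen_of_row[r]]]
    params <- draw_parameters(spec, locus_model)
    ds <- simulate_dataset(spec, params, plan, locus_model)
    stats_list[[r]] <- summary_statistics(ds)
    params_list[[r]] <- params
  }
  stats <- do.call(rbind, stats_list)
  if (anyNA(stats)) stop("missing summary statistic in reference table")
  mads <- apply(stats, 2L, stats::mad, constant = 1)
  if (any(mads == 0)) {
    warning("degenerate statistic(s) with zero MAD: ",
            paste(colnames(stats)[mads == 0], collapse = ", "))
    mads[mads == 0] <- 1
  }
  structure(
    list(stats = stats, scenario = factor(scen_of_row,
                                          levels = names(scenarios)),
         params = params_list, mad = mads, scenarios = scenarios,
         plan = plan, locus_model = locus_model, seed = seed),
    class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat("reference_table:", nrow(x$stats), "rows,",
      nlevels(x$scenario), "scenario(s),", ncol(x$stats), "statistics\n")
  invisible(x)
}

#' Retain the simulations closest to an observed dataset
#'
#' Euclidean distance on MAD-normalized summary statistics; the
#' `ceiling(fraction * rows)` smallest distances are retained, ties
#' broken by row index.
#'
#' @param table a [build_reference_table()] result.
#' @param observed observed summary-statistic vector (same names/order as
#'   the table columns).
#' @param fraction proportion of rows to retain, in (0, 1].
#' @return list with `idx` (retained row indices, closest first),
#'   `dist`, `scenario`, `params`, and `delta` (the largest retained
#'   distance).
#' @export
reject_closest <- function(table, observed, fraction) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  if (length(observed) != ncol(table$stats))
    stop("observed statistic vector length mismatch")
  z <- sweep(table$stats, 2L, table$mad, "/")
  zo <- observed / table$mad
  d <- sqrt(colSums((t(z) - zo)^2))
  keep <- order(d, seq_along(d))[seq_len(ceiling(fraction * nrow(table$stats)))]
  list(idx = keep, dist = d[keep],
       scenario = table$scenario[keep],
       params = table$params[keep],
       delta = max(d[keep]))
}

#' Direct scenario posterior from the closest simulations
#'
#' The posterior probability of each scenario is its share among the
#' `n_closest` retained simulations; 95% confidence intervals use the
#' normal approximation to the multinomial proportion.
#'
#' @param retained a [reject_closest()] result.
#' @param n_closest number of closest rows used (default 500, capped at
#'   the retained size).
#' @return data.frame `scenario`, `p`, `lo`, `hi`.
#' @export
posterior_direct <- function(retained, n_closest = 500L) {
  if (n_closest < 1L) stop("n_closest must be positive")
  n <- min(n_closest, length(retained$idx))
  sc <- retained$scenario[seq_len(n)]
  p <- as.numeric(table(sc)) / n
  se <- sqrt(p * (1 - p) / n)
  data.frame(scenario = levels(sc), p = p,
             lo = pmax(0, p - 1.96 * se),
             hi = pmin(1, p + 1.96 * se))
}

#' Logistic-regression scenario posterior
#'
#' Multinomial logistic regression of the scenario label on the
#' (normalized) deviation of each retained simulation's statistics from
#' the observed vector; scenario probabilities are the fitted values at
#' zero deviation, with 95% confidence intervals by the delta method.
#' Near-separated fits are refit with a small ridge penalty and flagged.
#'
#' @param table a [build_reference_table()] result.
#' @param observed observed summary-statistic vector.
#' @param fraction retained proportion (default 0.01).
#' @return data.frame `scenario`, `p`, `lo`, `hi`; attribute
#'   `regularized` is `TRUE` when the ridge refit was used.
#' @export
posterior_logistic <- function(table, observed, fraction = 0.01) {
  ret <- reject_closest(table, observed, fraction)
  sc <- droplevels(ret$scenario)
  if (nlevels(sc) < 2L)
    stop("fewer than 2 scenarios among retained rows; ",
         "logistic posterior undefined (direct posterior is 1/0)")
  z <- sweep(table$stats[ret$idx, , drop = FALSE], 2L, table$mad, "/")
  X <- sweep(z, 2L, observed / table$mad, "-")
  # drop directions without variation among retained rows
  keep <- apply(X, 2L, function(x) stats::sd(x) > 1e-12)
  X <- X[, keep, drop = FALSE]
  df <- data.frame(scenario = sc, X)
  fit <- nnet::multinom(scenario ~ ., data = df, trace = FALSE,
                        maxit = 500L, MaxNWts = 5000L)
  regularized <- FALSE
  co <- stats::coef(fit)
  if (any(!is.finite(co)) || max(abs(co)) > 25) {
    fit <- nnet::multinom(scenario ~ ., data = df, trace = FALSE,
                          maxit = 500L, MaxNWts = 5000L, decay = 1e-2)
    regularized <- TRUE
  }
  probs <- multinom_probs_at_origin(fit, nlevels(sc))
  ci <- multinom_ci_at_origin(fit, probs)
  all_sc <- levels(ret$scenario)
  p_full <- stats::setNames(rep(0, length(all_sc)), all_sc)
  lo <- hi <- p_full
  p_full[levels(sc)] <- probs
  lo[levels(sc)] <- ci$lo; hi[levels(sc)] <- ci$hi
  out <- data.frame(scenario = all_sc, p = unname(p_full),
                    lo = unname(lo), hi = unname(hi))
  attr(out, "regularized") <- regularized
  out
}

multinom_probs_at_origin <- function(fit, K) {
  co <- stats::coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1L)
  eta <- c(0, co[, 1L])  # intercepts; first level is the reference
  ex <- exp(eta - max(eta))
  ex / sum(ex)
}

multinom_ci_at_origin <- function(fit, probs) {
  K <- length(probs)
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V)))
    return(list(lo = pmax(0, probs - 0.5), hi = pmin(1, probs + 0.5)))
  nm <- colnames(V)
  # gradient of each p_k wrt the K-1 intercept coefficients
  ic <- grep("(Intercept)", nm, fixed = TRUE)
  lo <- hi <- numeric(K)
  for (k in seq_len(K)) {
    # dp_k / d eta_j = p_k (1[k = j] - p_j), j = 2..K (eta_1 fixed at 0)
    g <- numeric(length(nm))
    for (jj in seq_along(ic)) {
      j <- jj + 1L
      g[ic[jj]] <- probs[k] * ((k == j) - probs[j])
    }
    se <- sqrt(max(0, t(g) %*% V %*% g))
    lo[k] <- max(0, probs[k] - 1.96 * se)
    hi[k] <- min(1, probs[k] + 1.96 * se)
  }
  list(lo = lo, hi = hi)
}

logit <- function(x) log(x / (1 - x))
inv_logit <- function(x) 1 / (1 + exp(-x))

# map parameter values to the real line through their prior support
transform_param <- function(x, prior, eps = 1e-9) {
  if (prior$dist == "loguniform") {
    u <- (log(x) - log(prior$min)) / (log(prior$max) - log(prior$min))
  } else {
    u <- (x - prior$min) / (prior$max - prior$min)
  }
  logit(pmin(pmax(u, eps), 1 - eps))
}

back_transform_param <- function(z, prior) {
  u <- inv_logit(z)
  if (prior$dist == "loguniform") {
    exp(log(prior$min) + u * (log(prior$max) - log(prior$min)))
  } else {
    prior$min + u * (prior$max - prior$min)
  }
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  stats::approx(cw, x, xout = probs, rule = 2)$y
}

#' Posterior parameter estimation with local-linear adjustment
#'
#' Restricts the reference table to one scenario, retains the closest
#' fraction, maps each parameter to the real line by a logit of its
#' position inside the prior support, applies a weighted local-linear
#' (Epanechnikov kernel) regression adjustment of the retained values
#' toward the observed statistics, and back-transforms. Parameters piled
#' on a prior bound in more than half the retained rows skip the
#' adjustment and are flagged.
#'
#' @param table a [build_reference_table()] result.
#' @param observed observed summary-statistic vector.
#' @param fraction retained proportion among the scenario's rows.
#' @param scenario scenario name (default: the only scenario in the
#'   table).
#' @return data.frame `param`, `mean`, `median`, `q05`, `q95`,
#'   `adjusted`; attribute `posterior_sample` holds the adjusted draws
#'   and weights.
#' @export
estimate_parameters <- function(table, observed, fraction = 0.01,
                                scenario = NULL) {
  if (is.null(scenario)) {
    if (nlevels(table$scenario) != 1L)
      stop("scenario must be named for a multi-scenario table")
    scenario <- levels(table$scenario)[1L]
  }
  rows <- which(table$scenario == scenario)
  if (length(rows) == 0L) stop("no rows for scenario ", scenario)
  sub <- list(stats = table$stats[rows, , drop = FALSE],
              scenario = droplevels(table$scenario[rows]),
              params = table$params[rows], mad = table$mad)
  class(sub) <- "reference_table"
  ret <- reject_closest(sub, observed, fraction)
  nret <- length(ret$idx)
  if (nret < 200L)
    warning("only ", nret, " retained rows; quantiles will be noisy")
  spec <- table$scenarios[[scenario]]
  priors <- spec$priors
  lm_spec <- table$locus_model
  priors$mu <- list(dist = "uniform", min = lm_spec$mu_min,
                    max = lm_spec$mu_max)
  priors$P <- list(dist = "uniform", min = lm_spec$p_min,
                   max = lm_spec$p_max)
  pmat <- do.call(rbind, ret$params)
  pnames <- colnames(pmat)
  # Epanechnikov weights on the retained distances
  delta <- max(ret$dist)
  w <- if (delta > 0) 1 - (ret$dist / delta)^2 else rep(1, nret)
  w[w <= 0] <- min(w[w > 0], 1e-6)
  z <- sweep(sub$stats[ret$idx, , drop = FALSE], 2L, table$mad, "/")
  X <- sweep(z, 2L, observed / table$mad, "-")
  keep <- apply(X, 2L, function(x) stats::sd(x) > 1e-12)
  X <- X[, keep, drop = FALSE]
  # with few retained rows a full-rank regression would interpolate the
  # parameter values exactly; project onto leading principal components
  # so the adjustment keeps residual degrees of freedom
  max_dim <- max(1L, nret %/% 3L)
  if (ncol(X) > max_dim) {
    sv <- svd(X, nu = 0, nv = max_dim)
    X <- X %*% sv$v
  }
  out <- data.frame(param = pnames, mean = NA_real_, median = NA_real_,
                    q05 = NA_real_, q95 = NA_real_, adjusted = NA)
  sample_out <- matrix(NA_real_, nret, length(pnames),
                       dimnames = list(NULL, pnames))
  for (i in seq_along(pnames)) {
    pr <- priors[[pnames[i]]]
    if (is.null(pr)) stop("no prior bounds for parameter ", pnames[i])
    x <- pmat[, i]
    at_bound <- mean(x <= pr$min + 1e-12 | x >= pr$max - 1e-12)
    u <- transform_param(x, pr)
    if (at_bound > 0.5) {
      adj <- u
      out$adjusted[i] <- FALSE
    } else {
      fit <- stats::lm.wfit(cbind(1, X), u, w)
      beta <- fit$coefficients[-1L]
      beta[is.na(beta)] <- 0  # rank-deficient directions left unadjusted
      adj <- u - as.numeric(X %*% beta)
      out$adjusted[i] <- TRUE
    }
    vals <- back_transform_param(adj, pr)
    sample_out[, i] <- vals
    out$mean[i] <- sum(w * vals) / sum(w)
    qs <- weighted_quantile(vals, w, c(0.05, 0.5, 0.95))
    out$q05[i] <- qs[1L]; out$median[i] <- qs[2L]; out$q95[i] <- qs[3L]
  }
  attr(out, "posterior_sample") <- list(values = sample_out, weights = w)
  out
}

#' Winning scenario of a model choice
#'
#' The scenario with the top logistic-regression posterior probability;
#' when the retained rows all come from a single scenario (complete
#' separation in statistic space) that scenario wins outright.
#'
#' @param table a [build_reference_table()] result.
#' @param observed observed summary-statistic vector.
#' @param fraction retained proportion.
#' @return scenario name (character).
#' @export
top_scenario <- function(table, observed, fraction = 0.01) {
  ret <- reject_closest(table, observed, fraction)
  sc <- droplevels(ret$scenario)
  if (nlevels(sc) < 2L) return(levels(sc)[1L])
  post <- posterior_logistic(table, observed, fraction)
  post$scenario[which.max(post$p)]
}

#' Type I error of the scenario choice
#'
#' Fraction of pseudo-observed datasets simulated under the focal
#' scenario for which the focal scenario does not attain the top
#' logistic-regression posterior probability against the competitors.
#'
#' @param focal focal [scenario_spec()].
#' @param competitors list of competing [scenario_spec()] objects.
#' @param n_pods pseudo-observed datasets (default 500).
#' @param config list with `n_per_scenario`, `fraction`, `plan`,
#'   `locus_model`, `seed`; optionally a prebuilt `table`.
#' @return list with `rate`, `n_pods` and the per-pod winning scenario.
#' @export
type1_error <- function(focal, competitors, n_pods = 500L, config) {
  scn <- c(stats::setNames(list(focal), focal$name),
           stats::setNames(competitors,
                           vapply(competitors, function(s) s$name,
                                  character(1))))
  tab <- config$table %||%
    build_reference_table(scn, config$n_per_scenario, config$plan,
                          config$locus_model, config$seed)
  set.seed(config$seed + 1L)
  pod_seeds <- sample.int(.Machine$integer.max - 1L, n_pods)
  winners <- character(n_pods)
  for (i in seq_len(n_pods)) {
    set.seed(pod_seeds[i])
    params <- draw_parameters(focal, config$locus_model)
    pod <- simulate_dataset(focal, params, config$plan, config$locus_model)
    winners[i] <- top_scenario(tab, summary_statistics(pod),
                               config$fraction)
  }
  list(rate = mean(winners != focal$name), n_pods = n_pods,
       winners = winners, table = tab)
}

#' Type II error of the scenario choice
#'
#' For each competing scenario, the fraction of pseudo-observed datasets
#' simulated under that competitor for which the focal scenario wins the
#' logistic-regression model choice.
#'
#' @inheritParams type1_error
#' @return data.frame `competitor`, `rate`.
#' @export
type2_error <- function(focal, competitors, n_pods = 500L, config) {
  scn <- c(stats::setNames(list(focal), focal$name),
           stats::setNames(competitors,
                           vapply(competitors, function(s) s$name,
                                  character(1))))
  tab <- config$table %||%
    build_reference_table(scn, config$n_per_scenario, config$plan,
                          config$locus_model, config$seed)
  out <- data.frame(competitor = vapply(competitors, function(s) s$name,
                                        character(1)),
                    rate = NA_real_)
  for (ci in seq_along(competitors)) {
    comp <- competitors[[ci]]
    set.seed(config$seed + 1L + ci)
    pod_seeds <- sample.int(.Machine$integer.max - 1L, n_pods)
    focal_wins <- logical(n_pods)
    for (i in seq_len(n_pods)) {
      set.seed(pod_seeds[i])
      params <- draw_parameters(comp, config$locus_model)
      pod <- simulate_dataset(comp, params, config$plan,
                              config$locus_model)
      focal_wins[i] <- top_scenario(tab, summary_statistics(pod),
                                    config$fraction) == focal$name
    }
    out$rate[ci] <- mean(focal_wins)
  }
  attr(out, "table") <- tab
  out
}

#' Posterior-predictive model checking
#'
#' Simulates datasets with parameter vectors resampled from the adjusted
#' posterior and reports, per summary statistic, the fraction of
#' simulated values below the observed one; tail probabilities outside
#' (0.005, 0.995) flag a poorly fitted statistic (two-sided at the 1%
#' level).
#'
#' @param table a [build_reference_table()] result.
#' @param observed observed summary-statistic vector.
#' @param scenario scenario name.
#' @param fraction retained proportion for the posterior (default 0.01).
#' @param n_sims posterior-predictive simulations (default 1000).
#' @param seed seed for resampling and simulation.
#' @return data.frame `stat`, `observed`, `tail_prob`, `flagged`.
#' @export
model_check <- function(table, observed, scenario, fraction = 0.01,
                        n_sims = 1000L, seed = 1L) {
  est <- estimate_parameters(table, observed, fraction, scenario)
  ps <- attr(est, "posterior_sample")
  spec <- table$scenarios[[scenario]]
  set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)
  cons <- lapply(spec$constraints, parse_constraint)
  # adjusted draws can land outside the ordering constraints; resample
  valid <- which(vapply(seq_len(nrow(ps$values)), function(r)
    is.null(constraints_satisfied(as.list(ps$values[r, ]), cons)),
    logical(1)))
  if (length(valid) == 0L)
    stop("no constraint-satisfying posterior draws to resample from")
  draw_rows <- sample(valid, n_sims, replace = TRUE,
                      prob = ps$weights[valid])
  sims <- matrix(NA_real_, n_sims, length(observed))
  for (i in seq_len(n_sims)) {
    set.seed(sim_seeds[i])
    params <- ps$values[draw_rows[i], ]
    ds <- simulate_dataset(spec, params, table$plan, table$locus_model)
    sims[i, ] <- summary_statistics(ds)
  }
  tail_prob <- vapply(seq_along(observed), function(j)
    mean(sims[, j] < observed[j]), numeric(1))
  data.frame(stat = names(observed), observed = unname(observed),
             tail_prob = tail_prob,
             flagged = tail_prob < 0.005 | tail_prob > 0.995)
}

#' Convert coalescent generations to calendar years before present
#'
#' @param generations number of generations (scalar or vector).
#' @param gen_time_low,gen_time_high generation-time bounds in years
#'   (default 80 and 110, the range assumed for walnut).
#' @return matrix with columns `low`, `high` (years BP, rounded to the
#'   nearest year).
#' @export
generations_to_years <- function(generations, gen_time_low = 80,
                                 gen_time_high = 110) {
  if (any(generations < 0)) stop("generations must be non-negative")
  if (!(gen_time_low > 0 && gen_time_low <= gen_time_high))
    stop("need 0 < gen_time_low <= gen_time_high")
  cbind(low = round(generations * gen_time_low),
        high = round(generations * gen_time_high))
}
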