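#' Demographic scenario specification
#'
#' A scenario is a timeline of backward-time events over named gene pools:
#' `merge(t, source, sink)` (forward-time divergence of `source` out of
#' `sink`), `admix(t, derived, parentA, parentB, rate)` (forward-time
#' founding of `derived` by admixture; `rate` is the proportion of
#' lineages tracing to `parentA`), and `sizechange(t, pool, size)`
#' (forward-time size change at t). Every named parameter (pool sizes,
#' event times, admixture rates) carries a prior; strict inequalities
#' among time parameters express the historical ordering the scenario
#' assumes.
#'
#' @param name scenario identifier.
#' @param pools data.frame with columns `id` and `size` (size parameter
#'   name per pool).
#' @param events list of event lists; each has `type`, `time` (parameter
#'   name) and type-specific fields (`source`/`sink`, or
#'   `derived`/`parentA`/`parentB`/`rate`, or `pool`/`size`); `rate` and
#'   `size` fields name parameters.
#' @param priors named list; each element `list(dist, min, max)` with
#'   `dist` `"uniform"` or `"loguniform"`.
#' @param constraints character vector of strict inequalities between
#'   parameters, e.g. `"t4 > t3"`.
#' @param description free-text description.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, pools, events, priors, constraints = character(0),
                          description = "") {
  spec <- structure(
    list(name = name, pools = pools, events = events, priors = priors,
         constraints = as.character(constraints), description = description),
    class = "scenario_spec")
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("scenario_spec '", x$name, "': ", nrow(x$pools), " pools, ",
      length(x$events), " events, ", length(x$priors), " priors\n", sep = "")
  invisible(x)
}

scenario_params <- function(spec) {
  ref <- unique(c(
    spec$pools$size,
    unlist(lapply(spec$events, function(e) {
      switch(e$type,
             merge = e$time,
             admix = c(e$time, e$rate),
             sizechange = c(e$time, e$size),
             stop("unknown event type: ", e$type))
    }))))
  ref[!is.na(ref)]
}

parse_constraint <- function(s) {
  if (grepl(">", s, fixed = TRUE)) {
    p <- trimws(strsplit(s, ">", fixed = TRUE)[[1L]])
    c(gt = p[1L], lt = p[2L])
  } else if (grepl("<", s, fixed = TRUE)) {
    p <- trimws(strsplit(s, "<", fixed = TRUE)[[1L]])
    c(gt = p[2L], lt = p[1L])
  } else stop("cannot parse constraint: ", s)
}

#' Validate a scenario specification
#'
#' Checks that every referenced parameter has a prior, admixture-rate
#' priors sit inside (0, 1), every pool is terminated exactly once (merged
#' away or replaced by admixture) except a single final ancestor, each
#' terminated pool's lineages reach the final ancestor, and the ordering
#' constraints are acyclic.
#'
#' @param spec a [scenario_spec()].
#' @return the spec, invisibly, with events in constraint-consistent order
#'   where the constraint graph determines one.
#' @export
validate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  pars <- scenario_params(spec)
  missing_p <- setdiff(pars, names(spec$priors))
  if (length(missing_p))
    stop("scenario '", spec$name, "': no prior for parameter(s) ",
         paste(missing_p, collapse = ", "))
  for (nm in names(spec$priors)) {
    pr <- spec$priors[[nm]]
    if (!pr$dist %in% c("uniform", "loguniform"))
      stop("prior '", nm, "': unknown distribution ", pr$dist)
    if (!(pr$min < pr$max))
      stop("prior '", nm, "': lower bound must be below upper bound")
  }
  for (e in spec$events) {
    if (e$type == "admix") {
      pr <- spec$priors[[e$rate]]
      if (pr$min <= 0 || pr$max >= 1)
        stop("admixture rate prior '", e$rate, "' must lie inside (0, 1)")
    }
  }
  ids <- spec$pools$id
  term <- character(0); dest <- list()
  for (e in spec$events) {
    if (e$type == "merge") {
      if (e$source %in% term) stop("pool ", e$source, " terminated twice")
      term <- c(term, e$source); dest[[e$source]] <- e$sink
    } else if (e$type == "admix") {
      if (e$derived %in% term) stop("pool ", e$derived, " terminated twice")
      term <- c(term, e$derived); dest[[e$derived]] <- c(e$parentA, e$parentB)
    }
  }
  final <- setdiff(ids, term)
  if (length(final) != 1L)
    stop("scenario '", spec$name, "' must leave exactly one final ",
         "ancestral pool; found: ", paste(final, collapse = ", "))
  # every pool must reach the final ancestor through termination edges
  for (p in ids) {
    seen <- character(0); frontier <- p
    while (length(frontier)) {
      q <- frontier[1L]; frontier <- frontier[-1L]
      if (q %in% seen) next
      seen <- c(seen, q)
      if (!q %in% term) {
        if (q != final)
          stop("pool ", q, " is an orphan: never merged into the ancestor")
        next
      }
      frontier <- c(frontier, dest[[q]])
    }
    if (!final %in% seen)
      stop("pool ", p, " cannot reach the final ancestral pool")
  }
  # constraint graph must be acyclic
  cons <- lapply(spec$constraints, parse_constraint)
  nodes <- unique(unlist(cons))
  unknown <- setdiff(nodes, names(spec$priors))
  if (length(unknown))
    stop("constraint references unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  edges <- lapply(cons, function(x) c(x[["lt"]], x[["gt"]]))  # lt -> gt
  order_ok <- topo_sort(nodes, edges)
  if (is.null(order_ok))
    stop("ordering constraints form a cycle in scenario '", spec$name, "'")
  invisible(spec)
}

topo_sort <- function(nodes, edges) {
  if (length(nodes) == 0L) return(character(0))
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (e in edges) {
    adj[[e[1L]]] <- c(adj[[e[1L]]], e[2L])
    indeg[e[2L]] <- indeg[e[2L]] + 1L
  }
  out <- character(0)
  queue <- names(indeg)[indeg == 0L]
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

#' Locus mutation model for simulated SSR data
#'
#' @param n_loci number of unlinked loci.
#' @param motif repeat motif length in base pairs.
#' @param mu_min,mu_max bounds of the per-dataset uniform prior on the
#'   mutation rate per generation.
#' @param p_min,p_max bounds of the uniform prior on the GSM geometric
#'   parameter P.
#' @param range_clamp optional width (repeat units) of an allele-size
#'   window centred on the root size; `NULL` (default) leaves sizes
#'   unclamped.
#' @return an object of class `locus_model`.
#' @export
locus_model <- function(n_loci = 14L, motif = 2L, mu_min = 1e-4,
                        mu_max = 1e-3, p_min = 0.1, p_max = 0.3,
                        range_clamp = NULL) {
  stopifnot(mu_min > 0, mu_min < mu_max,
            p_min >= 0, p_max < 1, p_min <= p_max)
  structure(list(n_loci = as.integer(n_loci), motif = as.integer(motif),
                 mu_min = mu_min, mu_max = mu_max,
                 p_min = p_min, p_max = p_max, range_clamp = range_clamp),
            class = "locus_model")
}

draw_prior <- function(pr, n = 1L) {
  switch(pr$dist,
         uniform = stats::runif(n, pr$min, pr$max),
         loguniform = exp(stats::runif(n, log(pr$min), log(pr$max))),
         stop("unknown prior distribution: ", pr$dist))
}

constraints_satisfied <- function(params, cons) {
  for (cn in cons) {
    if (!(params[[cn[["gt"]]]] > params[[cn[["lt"]]]])) return(cn)
  }
  NULL
}

#' Draw a parameter vector from a scenario's priors
#'
#' Draws every parameter independently from its prior and rejects draws
#' violating the ordering constraints. If a `locus_model` is supplied, the
#' per-dataset mutation rate `mu` and GSM parameter `P` are appended.
#'
#' @param spec a validated [scenario_spec()].
#' @param locus_model optional [locus_model()].
#' @param max_tries bound on rejection retries before declaring the
#'   constraints inconsistent.
#' @return named numeric parameter vector.
#' @export
draw_parameters <- function(spec, locus_model = NULL, max_tries = 10000L) {
  cons <- lapply(spec$constraints, parse_constraint)
  for (i in seq_len(max_tries)) {
    params <- vapply(spec$priors, draw_prior, numeric(1))
    if (is.null(constraints_satisfied(params, cons))) {
      if (!is.null(locus_model)) {
        params <- c(params,
                    mu = stats::runif(1, locus_model$mu_min, locus_model$mu_max),
                    P = stats::runif(1, locus_model$p_min, locus_model$p_max))
      }
      return(params)
    }
  }
  stop("constraint acceptance rate below 1/", max_tries,
       " in scenario '", spec$name, "': priors and constraints inconsistent")
}

#' Simulate a genotype dataset under a demographic scenario
#'
#' Runs the coalescent kernel once per locus under the realized event
#' timeline and forms diploid genotypes by pairing consecutive gene copies
#' within each sampled pool.
#'
#' @param spec a validated [scenario_spec()].
#' @param params named parameter vector (see [draw_parameters()]); must
#'   contain `mu` and `P` unless given in `...`-free form, in which case
#'   they are drawn from `locus_model`.
#' @param plan named integer vector: diploid sample size per sampled pool.
#' @param locus_model a [locus_model()].
#' @param seed optional integer seed.
#' @return a [genotype_dataset()].
#' @export
simulate_dataset <- function(spec, params, plan, locus_model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cons <- lapply(spec$constraints, parse_constraint)
  bad <- constraints_satisfied(params, cons)
  if (!is.null(bad))
    stop("parameter vector violates constraint ",
         bad[["gt"]], " > ", bad[["lt"]])
  if (!all(names(plan) %in% spec$pools$id))
    stop("sampling plan names unknown pool(s)")
  mu <- if ("mu" %in% names(params)) params[["mu"]] else
    stats::runif(1, locus_model$mu_min, locus_model$mu_max)
  P <- if ("P" %in% names(params)) params[["P"]] else
    stats::runif(1, locus_model$p_min, locus_model$p_max)

  pool_sizes <- stats::setNames(as.numeric(params[spec$pools$size]),
                                spec$pools$id)
  events <- lapply(spec$events, function(e) {
    out <- list(type = e$type, time = params[[e$time]])
    if (e$type == "merge") { out$source <- e$source; out$sink <- e$sink }
    if (e$type == "admix") {
      out$derived <- e$derived; out$parentA <- e$parentA
      out$parentB <- e$parentB; out$rate <- params[[e$rate]]
    }
    if (e$type == "sizechange") { out$pool <- e$pool; out$size <- params[[e$size]] }
    out
  })
  samples <- stats::setNames(as.integer(2L * plan), names(plan))
  nloc <- locus_model$n_loci
  ntot_ind <- sum(plan)
  alleles <- matrix(NA_integer_, nrow = ntot_ind, ncol = 2L * nloc)
  pop <- rep(names(plan), times = plan)
  for (j in seq_len(nloc)) {
    loc <- sim_locus(samples, pool_sizes, events, mu = mu, p_geom = P)
    units <- loc$sizes
    if (!is.null(locus_model$range_clamp)) {
      half <- locus_model$range_clamp / 2
      units <- pmin(pmax(units, 100 - half), 100 + half)
    }
    bp <- as.integer(units) * locus_model$motif
    # consecutive gene copies within a pool form one diploid individual
    a1 <- bp[seq(1L, length(bp), 2L)]
    a2 <- bp[seq(2L, length(bp), 2L)]
    alleles[, 2L * j - 1L] <- a1
    alleles[, 2L * j] <- a2
  }
  loci <- data.frame(name = paste0("L", seq_len(nloc)),
                     motif = locus_model$motif)
  genotype_dataset(alleles, pop, loci = loci, populations = names(plan))
}

#' Read a scenario file
#'
#' Scenario files are YAML: `name`, `pools` (list of `{id, size}`),
#' `events`, `priors` and `constraints`, mirroring [scenario_spec()].
#'
#' @param path path to a scenario `.yaml` file.
#' @return a validated [scenario_spec()].
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  pools <- do.call(rbind, lapply(y$pools, function(p)
    data.frame(id = p$id, size = p$size, stringsAsFactors = FALSE)))
  priors <- lapply(y$priors, function(p)
    list(dist = p$dist, min = as.numeric(p$min), max = as.numeric(p$max)))
  spec <- scenario_spec(y$name, pools, y$events, priors,
                        constraints = unlist(y$constraints) %||% character(0),
                        description = y$description %||% "")
  validate_scenario(spec)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shipped demographic scenario fixtures
#'
#' Loads the ten walnut dispersal scenarios (broad-scale 1a-5a, fine-scale
#' 1b-6b) shipped with the package.
#'
#' @param names optional subset of scenario names (e.g. `"scenario_6b"`).
#' @return named list of validated [scenario_spec()] objects.
#' @export
walnut_scenarios <- function(names = NULL) {
  dir <- system.file("extdata", "scenarios", package = "walnutpg")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  specs <- lapply(files, read_scenario)
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  if (!is.null(names)) {
    missing_s <- setdiff(names, names(specs))
    if (length(missing_s))
      stop("unknown scenario(s): ", paste(missing_s, collapse = ", "))
    specs <- specs[names]
  }
  specs
}

#' Published stage-2 posterior summaries for scenario 6b
#'
#' Posterior mean, median and 90% interval of the demographic parameters
#' of the best-supported walnut dispersal scenario (effective sizes in
#' diploid individuals, times in generations, admixture rates as
#' proportions), as published for the European walnut analysis. These
#' values drive the generation-to-year conversions and the derived
#' decline fraction in the analysis scripts.
#'
#' @return data.frame with columns `param`, `description`, `mean`,
#'   `median`, `q05`, `q95`.
#' @export
walnut_published_posterior <- function() {
  f <- system.file("extdata", "walnut_stage2_posterior.csv",
                   package = "walnutpg")
  utils::read.csv(f, comment.char = "#", stringsAsFactors = FALSE)
}

#' Four-pool sampling plan used in the walnut ABC analyses
#'
#' Diploid sample sizes of the four gene pools compared by the demographic
#' analysis: Anatolia (41), the Balkans (131), northeastern Europe (279)
#' and western Europe (650).
#'
#' @return named integer vector.
#' @export
walnut_sampling_plan <- function() {
  c(pool1 = 41L, pool2 = 131L, pool3 = 279L, pool4 = 650L)
}
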