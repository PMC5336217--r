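#' @name coalescent-core
#' @title Coalescent simulation core
#'
#' @description
#' A single continuous-time coalescent kernel drives every simulator in the
#' package: the demographic-scenario engine of the ABC machinery, the
#' island-model genotype generator, and the single-population equilibrium
#' simulations behind the bottleneck tests. Time runs backwards in
#' generations; within a pool of diploid effective size N, each pair of
#' lineages coalesces at rate 1/(2N), i.e. k lineages coalesce at total
#' rate k(k-1)/(4N). Demographic events (pool mergers, admixture splits,
#' size changes) are instantaneous. Mutations are laid on branches as a
#' Poisson process and shift the allele size on a repeat-unit ladder; the
#' default step distribution is the generalized stepwise model (GSM):
#' geometric step magnitudes on {1, 2, ...} with parameter 1 - P
#' (mean 1/(1-P)), sign fair.
NULL

# signed GSM steps: geometric magnitudes, fair sign
gsm_steps <- function(nmut, p_geom) {
  if (nmut == 0L) return(integer(0))
  mag <- 1L + stats::rgeom(nmut, prob = 1 - p_geom)
  mag * sample(c(-1L, 1L), nmut, replace = TRUE)
}

make_gsm_sampler <- function(p_geom) {
  force(p_geom)
  function(nmut) gsm_steps(nmut, p_geom)
}

#' Simulate one locus under a demographic event timeline
#'
#' Low-level kernel. Lineages start in sampled pools at time 0 and coalesce
#' backwards through the event timeline; after the tree is complete,
#' mutations are placed on branches and allele sizes propagated from the
#' root.
#'
#' @param samples named integer vector: gene copies sampled per pool at
#'   time 0.
#' @param pool_sizes named numeric vector: diploid effective size of every
#'   pool that is ever active.
#' @param events list of events sorted by time, each a list with `time`
#'   (generations) and `type` one of `"merge"` (`source`, `sink`),
#'   `"admix"` (`derived`, `parentA`, `parentB`, `rate` = probability a
#'   lineage traces to `parentA`), `"sizechange"` (`pool`, `size`).
#' @param mu mutation rate per gene copy per generation.
#' @param step_sampler function(nmut) returning `nmut` signed integer
#'   steps in repeat units; default GSM with `p_geom`.
#' @param p_geom GSM geometric parameter P (ignored if `step_sampler`
#'   given).
#' @param migration per-lineage migration rate per generation to a
#'   uniformly chosen other pool (island model); 0 for scenario timelines.
#' @param root_size allele size of the most recent common ancestor, in
#'   repeat units.
#' @return list with `sizes` (allele size per sampled gene copy, repeat
#'   units) and `pool` (pool ID per gene copy).
#' @export
sim_locus <- function(samples, pool_sizes, events = list(), mu,
                      step_sampler = NULL, p_geom = 0, migration = 0,
                      root_size = 100L) {
  pools <- names(pool_sizes)
  if (is.null(pools)) stop("pool_sizes must be named")
  if (!all(names(samples) %in% pools))
    stop("sampled pool not in pool_sizes")
  if (is.null(step_sampler)) step_sampler <- make_gsm_sampler(p_geom)
  npool <- length(pools)
  sizes <- as.numeric(pool_sizes)
  active_pool <- rep(TRUE, npool)

  n <- sum(samples)
  if (n < 1L) stop("no gene copies sampled")
  ntot <- 2L * n - 1L
  parent <- integer(ntot)
  node_time <- numeric(ntot)
  # lineage state
  lin_nodes <- seq_len(n)
  lin_pool <- rep(match(names(samples), pools), times = samples)
  leaf_pool <- pools[lin_pool]

  ev_times <- vapply(events, function(e) as.numeric(e$time), numeric(1))
  ev_order <- order(ev_times, seq_along(ev_times))
  events <- events[ev_order]; ev_times <- ev_times[ev_order]
  ev_i <- 1L; nev <- length(events)

  t <- 0; nxt <- n + 1L
  while (length(lin_nodes) > 1L) {
    # after the last event every lineage sits in one pool; finish lean
    if (ev_i > nev && migration == 0 &&
        all(lin_pool == lin_pool[1L])) {
      Np <- sizes[lin_pool[1L]]
      if (!is.finite(Np) || Np <= 0)
        stop("final pool has no finite size")
      k <- length(lin_nodes)
      while (k > 1L) {
        t <- t + stats::rexp(1L, k * (k - 1) / (4 * Np))
        pair <- sample.int(k, 2L)
        node_time[nxt] <- t
        parent[lin_nodes[pair]] <- nxt
        lin_nodes[pair[1L]] <- nxt
        lin_nodes <- lin_nodes[-pair[2L]]
        nxt <- nxt + 1L; k <- k - 1L
      }
      break
    }
    k <- tabulate(lin_pool, npool)
    coal <- k * (k - 1) / (4 * sizes)
    coal[!is.finite(coal)] <- 0
    mig_tot <- if (migration > 0 && sum(active_pool) > 1L)
      length(lin_nodes) * migration else 0
    tot <- sum(coal) + mig_tot
    t_ev <- if (ev_i <= nev) ev_times[ev_i] else Inf
    dt <- if (tot > 0) stats::rexp(1L, tot) else Inf
    if (t + dt >= t_ev) {
      if (is.infinite(t_ev))
        stop("lineages cannot coalesce: zero rate and no pending events")
      t <- t_ev
      e <- events[[ev_i]]; ev_i <- ev_i + 1L
      if (e$type == "merge") {
        src <- match(e$source, pools); snk <- match(e$sink, pools)
        if (is.na(src) || is.na(snk)) stop("merge names unknown pool")
        if (!active_pool[snk]) stop("merge into inactive pool ", e$sink)
        lin_pool[lin_pool == src] <- snk
        active_pool[src] <- FALSE
      } else if (e$type == "admix") {
        der <- match(e$derived, pools)
        pa <- match(e$parentA, pools); pb <- match(e$parentB, pools)
        if (is.na(der) || is.na(pa) || is.na(pb))
          stop("admix names unknown pool")
        if (!active_pool[pa] || !active_pool[pb])
          stop("admixture parent inactive")
        sel <- which(lin_pool == der)
        goA <- stats::runif(length(sel)) < e$rate
        lin_pool[sel[goA]] <- pa
        lin_pool[sel[!goA]] <- pb
        active_pool[der] <- FALSE
      } else if (e$type == "sizechange") {
        pl <- match(e$pool, pools)
        if (is.na(pl)) stop("sizechange names unknown pool")
        sizes[pl] <- as.numeric(e$size)
      } else stop("unknown event type: ", e$type)
      next
    }
    t <- t + dt
    u <- stats::runif(1L) * tot
    cum <- cumsum(coal)
    hit <- which(u <= cum)
    if (length(hit) > 0L) {
      p <- hit[1L]
      idx <- which(lin_pool == p)
      pair <- if (length(idx) == 2L) idx else sample(idx, 2L)
      node <- nxt; nxt <- nxt + 1L
      node_time[node] <- t
      parent[lin_nodes[pair]] <- node
      lin_nodes[pair[1L]] <- node
      lin_nodes <- lin_nodes[-pair[2L]]
      lin_pool <- lin_pool[-pair[2L]]
    } else {
      i <- sample.int(length(lin_nodes), 1L)
      others <- which(active_pool & seq_len(npool) != lin_pool[i])
      if (length(others) > 0L)
        lin_pool[i] <- if (length(others) == 1L) others else sample(others, 1L)
    }
  }

  # mutations and allele sizes; parent index always exceeds child index
  alleles <- integer(ntot)
  alleles[ntot] <- as.integer(root_size)
  if (ntot > 1L) {
    ch <- seq_len(ntot - 1L)
    lens <- node_time[parent[ch]] - node_time[ch]
    nm <- stats::rpois(ntot - 1L, lens * mu)
    tot_m <- sum(nm)
    delta <- integer(ntot - 1L)
    if (tot_m > 0L) {
      steps <- step_sampler(tot_m)
      who <- rep.int(ch, nm)
      d <- rowsum(steps, who)
      delta[as.integer(rownames(d))] <- as.integer(d[, 1L])
    }
    for (i in (ntot - 1L):1L)
      alleles[i] <- alleles[parent[i]] + delta[i]
  }
  list(sizes = alleles[seq_len(n)], pool = leaf_pool)
}

#' Simulate one locus in a single equilibrium population
#'
#' Fast path for a single panmictic pool of constant size, used by the
#' bottleneck equilibrium simulations. Time is scaled in units of 2N
#' generations, so the only parameter is theta = 4 N mu.
#'
#' @param n gene copies sampled.
#' @param theta scaled mutation rate 4 N mu.
#' @param step_sampler function(nmut) -> signed steps (default strict SMM).
#' @param root_size ancestral allele size in repeat units.
#' @return integer vector of `n` allele sizes.
#' @export
sim_single_pop <- function(n, theta, step_sampler = NULL, root_size = 100L) {
  if (n < 1L) stop("need at least one gene copy")
  if (is.null(step_sampler)) step_sampler <- make_gsm_sampler(0)
  ntot <- 2L * n - 1L
  parent <- integer(ntot); node_time <- numeric(ntot)
  lin <- seq_len(n); t <- 0; nxt <- n + 1L
  k <- n
  while (k > 1L) {
    t <- t + stats::rexp(1L, k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    node_time[nxt] <- t
    parent[lin[pair]] <- nxt
    lin[pair[1L]] <- nxt
    lin <- lin[-pair[2L]]
    nxt <- nxt + 1L; k <- k - 1L
  }
  alleles <- integer(ntot)
  alleles[ntot] <- as.integer(root_size)
  if (ntot > 1L) {
    ch <- seq_len(ntot - 1L)
    lens <- node_time[parent[ch]] - node_time[ch]
    nm <- stats::rpois(ntot - 1L, lens * theta / 2)
    tot_m <- sum(nm)
    delta <- integer(ntot - 1L)
    if (tot_m > 0L) {
      steps <- step_sampler(tot_m)
      who <- rep.int(ch, nm)
      d <- rowsum(steps, who)
      delta[as.integer(rownames(d))] <- as.integer(d[, 1L])
    }
    for (i in (ntot - 1L):1L)
      alleles[i] <- alleles[parent[i]] + delta[i]
  }
  alleles[seq_len(n)]
}
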