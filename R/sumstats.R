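#' ABC summary statistics for a multi-pool genotype dataset
#'
#' The statistic families summarizing observed and simulated datasets for
#' the demographic inference: per pool, the mean allele count, mean
#' unbiased expected heterozygosity and mean allele-size variance per
#' locus; per unordered pool pair, the multilocus Weir-Cockerham FST and
#' the mean allele-shared classification index; per ordered pool pair
#' (i to j), the mean log10 assignment likelihood of pool i's genotypes
#' under pool j's (add-one smoothed) allele frequencies. For four pools
#' the vector has 3*4 + 6 + 12 + 6 = 36 entries.
#'
#' @param dataset a [genotype_dataset()]; each population is one pool
#'   unless `pools` maps populations to pools.
#' @param pools optional named vector mapping population ID to pool ID.
#' @return named numeric vector of summary statistics.
#' @export
summary_statistics <- function(dataset, pools = NULL) {
  ds <- if (is.null(pools)) dataset else pool_populations(dataset, pools)
  ids <- ds$populations
  P <- length(ids)
  nloc <- n_loci(ds)
  if (P < 2L) stop("need at least 2 pools for between-pool statistics")
  small <- table(factor(ds$pop, levels = ids)) < 2L
  if (any(small))
    stop("pool(s) with fewer than 2 individuals: ",
         paste(ids[small], collapse = ", "))

  # per-locus summaries reused by all stat families
  sums <- lapply(seq_len(nloc), function(j) locus_popsummary(ds, j))
  loc_m <- lapply(seq_len(nloc), function(j) locus_alleles(ds, j))
  popf <- factor(ds$pop, levels = ids)

  nal <- het <- vsz <- matrix(NA_real_, nloc, P)
  for (j in seq_len(nloc)) {
    s <- sums[[j]]
    if (is.null(s)) next
    for (i in seq_len(P)) {
      n <- s$n[i]
      if (n < 1L) next
      p <- s$p[, i]
      nal[j, i] <- sum(p > 0)
      het[j, i] <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
      m <- loc_m[[j]]
      sel <- popf == ids[i] & !is.na(m[, 1L])
      sizes <- c(m[sel, 1L], m[sel, 2L])
      if (length(sizes) >= 2L) vsz[j, i] <- stats::var(sizes)
    }
  }
  out <- numeric(0)
  for (i in seq_len(P)) {
    out[paste0("nal_", ids[i])] <- mean(nal[, i], na.rm = TRUE)
    out[paste0("het_", ids[i])] <- mean(het[, i], na.rm = TRUE)
    out[paste0("vsz_", ids[i])] <- mean(vsz[, i], na.rm = TRUE)
  }
  # pairwise WC FST from the per-locus summaries
  for (a in seq_len(P - 1L)) for (b in (a + 1L):P) {
    A <- B <- C <- 0
    for (j in seq_len(nloc)) {
      s <- sums[[j]]
      if (is.null(s) || length(s$alleles) < 2L) next
      comp <- wc_components(s$n[c(a, b)], s$p[, c(a, b), drop = FALSE],
                            s$h[, c(a, b), drop = FALSE])
      if (is.null(comp)) next
      A <- A + sum(comp[, "a"]); B <- B + sum(comp[, "b"])
      C <- C + sum(comp[, "c"])
    }
    tot <- A + B + C
    out[paste0("fst_", ids[a], "_", ids[b])] <-
      if (tot > 0) A / tot else 0
  }
  # mean log10 assignment likelihood, ordered pairs
  lik <- assignment_likelihoods(ds, sums, loc_m, popf)
  for (a in seq_len(P)) for (b in seq_len(P)) {
    if (a == b) next
    out[paste0("lik_", ids[a], "_", ids[b])] <- lik[a, b]
  }
  # mean allele-shared classification index, unordered pairs
  for (a in seq_len(P - 1L)) for (b in (a + 1L):P) {
    out[paste0("das_", ids[a], "_", ids[b])] <-
      classification_index(ds, loc_m, popf, a, b)
  }
  out
}

# mean over pool-a individuals of the summed (over loci) log10 genotype
# likelihood under pool-b frequencies, add-one smoothed over the locus's
# dataset-wide allele set
assignment_likelihoods <- function(ds, sums, loc_m, popf) {
  ids <- ds$populations; P <- length(ids); nloc <- n_loci(ds)
  acc <- matrix(0, n_individuals(ds), P)
  for (j in seq_len(nloc)) {
    s <- sums[[j]]
    if (is.null(s)) next
    alleles <- s$alleles
    K <- length(alleles)
    m <- loc_m[[j]]
    kept <- which(!is.na(m[, 1L]))
    counts <- sweep(s$p, 2L, 2 * s$n, "*")
    sm <- sweep(counts + 1, 2L, 2 * s$n + K, "/")
    i1 <- match(m[kept, 1L], alleles)
    i2 <- match(m[kept, 2L], alleles)
    hetv <- i1 != i2
    for (b in seq_len(P)) {
      pb <- sm[, b]
      acc[kept, b] <- acc[kept, b] +
        log10(pb[i1]) + log10(pb[i2]) + ifelse(hetv, log10(2), 0)
    }
  }
  out <- matrix(0, P, P)
  for (a in seq_len(P))
    out[a, ] <- colMeans(acc[popf == ids[a], , drop = FALSE])
  out
}

# shared-allele distance between all individuals of two pools, per locus;
# DAS(x, y) = 1 - shared / (2 * loci counted)
das_matrix <- function(ds, loc_m, idx_a, idx_b) {
  nloc <- n_loci(ds)
  shared <- matrix(0, length(idx_a), length(idx_b))
  nl <- matrix(0, length(idx_a), length(idx_b))
  for (j in seq_len(nloc)) {
    m <- loc_m[[j]]
    xa1 <- m[idx_a, 1L]; xa2 <- m[idx_a, 2L]
    xb1 <- m[idx_b, 1L]; xb2 <- m[idx_b, 2L]
    ok <- outer(!is.na(xa1), !is.na(xb1), "&")
    e11 <- outer(xa1, xb1, "=="); e12 <- outer(xa1, xb2, "==")
    e21 <- outer(xa2, xb1, "=="); e22 <- outer(xa2, xb2, "==")
    hom_a <- xa1 == xa2
    # multiset intersection of the two allele pairs
    s_het <- (e11 | e12) + (e21 | e22)
    s_hom <- pmin(2, e11 + e12)
    sj <- ifelse(matrix(hom_a, length(idx_a), length(idx_b)), s_hom, s_het)
    sj[!ok] <- 0
    shared <- shared + sj
    nl <- nl + ok
  }
  1 - shared / (2 * pmax(nl, 1))
}

# fraction of pool-a individuals closer (mean DAS) to their own pool than
# to pool b, averaged with the reverse direction
classification_index <- function(ds, loc_m, popf, a, b) {
  idx_a <- which(as.integer(popf) == a)
  idx_b <- which(as.integer(popf) == b)
  daa <- das_matrix(ds, loc_m, idx_a, idx_a)
  dbb <- das_matrix(ds, loc_m, idx_b, idx_b)
  dab <- das_matrix(ds, loc_m, idx_a, idx_b)
  own_a <- (rowSums(daa) - diag(daa)) / (length(idx_a) - 1L)
  own_b <- (rowSums(dbb) - diag(dbb)) / (length(idx_b) - 1L)
  # exact ties (e.g. indistinguishable pools) get half credit
  frac_a <- mean(own_a < rowMeans(dab)) + 0.5 * mean(own_a == rowMeans(dab))
  frac_b <- mean(own_b < colMeans(dab)) + 0.5 * mean(own_b == colMeans(dab))
  (frac_a + frac_b) / 2
}
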