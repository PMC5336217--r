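#' @name fstats
#' @title Weir-Cockerham F-statistics and Jost's D
#'
#' @description
#' Multi-allelic Weir & Cockerham (1984) variance-component estimators of
#' Wright's fixation indices: the within-population inbreeding coefficient
#' f (FIS), the total inbreeding coefficient F (FIT) and the
#' among-population differentiation theta (FST). Components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals) are computed per allele and locus; multi-locus estimates
#' are ratios of summed components, never means of per-locus ratios.
NULL

# per-locus summaries used by the WC84 components:
#   n: individuals typed per population
#   p: allele-frequency matrix (alleles x populations)
#   h: per-allele observed-heterozygote frequency matrix (alleles x pops),
#      i.e. the fraction of typed individuals heterozygous AND carrying
#      that allele
locus_popsummary <- function(ds, j) {
  m <- locus_alleles(ds, j)
  keep <- !is.na(m[, 1L])
  if (!any(keep)) return(NULL)
  popf <- factor(ds$pop[keep], levels = ds$populations)
  a1 <- m[keep, 1L]; a2 <- m[keep, 2L]
  alleles <- sort(unique(c(a1, a2)))
  af <- factor(c(a1, a2), levels = alleles)
  cnt <- table(af, factor(rep(ds$pop[keep], 2L), levels = ds$populations))
  n <- as.integer(table(popf))
  p <- sweep(matrix(as.numeric(cnt), nrow = length(alleles),
                    dimnames = list(alleles, ds$populations)),
             2L, pmax(2L * n, 1L), "/")
  het <- a1 != a2
  h <- matrix(0, nrow = length(alleles), ncol = length(ds$populations),
              dimnames = list(alleles, ds$populations))
  if (any(het)) {
    hf1 <- table(factor(a1[het], levels = alleles), popf[het])
    hf2 <- table(factor(a2[het], levels = alleles), popf[het])
    h <- sweep(matrix(as.numeric(hf1 + hf2), nrow = length(alleles)),
               2L, pmax(n, 1L), "/")
    dimnames(h) <- list(alleles, ds$populations)
  }
  list(n = n, p = p, h = h, alleles = alleles)
}

# WC84 variance components for one locus given per-population summaries;
# returns per-allele a, b, c (rows = alleles)
wc_components <- function(n, p, h) {
  use <- n >= 1L
  n <- n[use]; p <- p[, use, drop = FALSE]; h <- h[, use, drop = FALSE]
  r <- length(n)
  if (r < 2L) return(NULL)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- as.numeric(p %*% n) / (r * nbar)
  s2 <- as.numeric(((p - pbar)^2) %*% n) / ((r - 1) * nbar)
  hbar <- as.numeric(h %*% n) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  cbind(a = a, b = b, c = cc)
}

#' Weir-Cockerham F-statistics
#'
#' @param dataset a [genotype_dataset()] with at least two populations.
#' @return list with `per_locus` (data.frame of f, F, theta per locus) and
#'   `overall` (named vector `f`, `F`, `theta` from summed components).
#' @export
wc_fstats <- function(dataset) {
  if (n_populations(dataset) < 2L)
    stop("need at least two populations")
  nloc <- n_loci(dataset)
  per <- data.frame(locus = dataset$loci$name, f = NA_real_, F = NA_real_,
                    theta = NA_real_)
  A <- B <- C <- 0
  for (j in seq_len(nloc)) {
    s <- locus_popsummary(dataset, j)
    if (is.null(s) || length(s$alleles) < 2L) next
    comp <- wc_components(s$n, s$p, s$h)
    if (is.null(comp)) next
    sa <- sum(comp[, "a"]); sb <- sum(comp[, "b"]); sc <- sum(comp[, "c"])
    tot <- sa + sb + sc
    if (tot > 0) {
      per$theta[j] <- sa / tot
      per$F[j] <- 1 - sc / tot
      if (sb + sc > 0) per$f[j] <- 1 - sc / (sb + sc)
    }
    A <- A + sa; B <- B + sb; C <- C + sc
  }
  tot <- A + B + C
  overall <- c(f = if (B + C > 0) 1 - C / (B + C) else NA_real_,
               F = if (tot > 0) 1 - C / tot else NA_real_,
               theta = if (tot > 0) A / tot else NA_real_)
  list(per_locus = per, overall = overall)
}

#' Pairwise multilocus FST matrix
#'
#' Weir-Cockerham theta for every population pair.
#'
#' @param dataset a [genotype_dataset()].
#' @return symmetric matrix with zero diagonal; pairs with no shared
#'   polymorphic locus are `NA` (flagged via a warning).
#' @export
pairwise_fst <- function(dataset) {
  pops <- dataset$populations
  k <- length(pops)
  out <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    sub <- subset_populations(dataset, pops[c(i, j)])
    th <- tryCatch(wc_fstats(sub)$overall[["theta"]],
                   error = function(e) NA_real_)
    if (is.na(th))
      warning("FST undefined for pair ", pops[i], " / ", pops[j])
    out[i, j] <- out[j, i] <- th
  }
  out
}

#' Jost's D differentiation estimator
#'
#' Unbiased D per locus from Nei-Chesser-corrected within- and
#' total-heterozygosity (harmonic-mean sample size), and combined across
#' loci by the harmonic mean of per-locus values (arithmetic mean also
#' reported).
#'
#' @param dataset a [genotype_dataset()] with at least two populations.
#' @return list with `per_locus` data.frame (`locus`, `D`) and `combined`
#'   named vector (`harmonic`, `arithmetic`).
#' @export
jost_d <- function(dataset) {
  if (n_populations(dataset) < 2L)
    stop("need at least two populations")
  nloc <- n_loci(dataset)
  D <- rep(NA_real_, nloc)
  for (j in seq_len(nloc)) {
    s <- locus_popsummary(dataset, j)
    if (is.null(s)) next
    use <- s$n >= 1L
    n <- s$n[use]; p <- s$p[, use, drop = FALSE]
    npop <- length(n)
    if (npop < 2L) next
    ntilde <- npop / sum(1 / n)  # harmonic mean sample size (individuals)
    hs_obs <- 1 - mean(colSums(p^2))
    hs <- (2 * ntilde / (2 * ntilde - 1)) * hs_obs
    pbar <- rowMeans(p)
    ht_obs <- 1 - sum(pbar^2)
    ht <- ht_obs + hs / (2 * ntilde * npop)
    if (hs >= 1) { warning("Jost's D undefined at locus ",
                           dataset$loci$name[j], " (Hs = 1)"); next }
    D[j] <- (npop / (npop - 1)) * (ht - hs) / (1 - hs)
  }
  ok <- !is.na(D)
  pos <- ok & D > 0
  harm <- if (any(pos)) sum(pos) / sum(1 / D[pos]) else 0
  list(per_locus = data.frame(locus = dataset$loci$name, D = D),
       combined = c(harmonic = harm, arithmetic = mean(D[ok])))
}
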