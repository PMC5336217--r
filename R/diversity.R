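#' Per-locus diversity summary over the pooled sample
#'
#' Allele counts, effective allele number, observed/expected
#' heterozygosity and polymorphic information content per locus, with
#' allele frequencies pooled over populations.
#'
#' @param dataset a [genotype_dataset()].
#' @return data.frame with columns `locus`, `A`, `Ae`, `Ho`, `HE`, `PIC`
#'   and a `mean` attribute row appended via `attr(, "means")`.
#' @export
locus_summary <- function(dataset) {
  nloc <- n_loci(dataset)
  out <- data.frame(locus = dataset$loci$name, A = NA_integer_,
                    Ae = NA_real_, Ho = NA_real_, HE = NA_real_,
                    PIC = NA_real_)
  for (j in seq_len(nloc)) {
    m <- locus_alleles(dataset, j)
    keep <- !is.na(m[, 1L])
    if (!any(keep)) {
      warning("locus ", dataset$loci$name[j], " has no genotypes; undefined")
      next
    }
    a1 <- m[keep, 1L]; a2 <- m[keep, 2L]
    cnt <- table(c(a1, a2))
    p <- as.numeric(cnt) / sum(cnt)
    sp2 <- sum(p^2); sp4 <- sum(p^4)
    out$A[j] <- length(p)
    out$Ae[j] <- 1 / sp2
    out$Ho[j] <- mean(a1 != a2)
    out$HE[j] <- 1 - sp2
    out$PIC[j] <- 1 - sp2 - (sp2^2 - sp4)
  }
  attr(out, "means") <- colMeans(out[, -1L], na.rm = TRUE)
  out
}

#' Expected allele count in a rarefied subsample
#'
#' Hypergeometric rarefaction: the expected number of distinct alleles in
#' a random draw of `g` gene copies from the observed copies.
#'
#' @param counts per-allele gene-copy counts.
#' @param g rarefaction size in gene copies.
#' @return expected allele count (between 1 and `length(counts)` for
#'   polymorphic input).
#' @export
rarefied_allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g > N) stop("rarefaction size g = ", g, " exceeds sample size ", N)
  if (g < 1) stop("g must be at least 1")
  # P(allele i absent) = C(N - Ni, g) / C(N, g)
  absent <- exp(lchoose(N - counts, g) - lchoose(N, g))
  absent[N - counts < g] <- 0
  sum(1 - absent)
}

#' Expected private allele count in rarefied subsamples
#'
#' The rarefied expected number of alleles present in a population's
#' subsample of `g` gene copies and absent from every other population's
#' subsample of the same size.
#'
#' @param counts_by_pop matrix of gene-copy counts (rows = alleles,
#'   columns = populations).
#' @param g rarefaction size in gene copies.
#' @return named numeric vector of expected private allele counts.
#' @export
rarefied_private_richness <- function(counts_by_pop, g) {
  m <- as.matrix(counts_by_pop)
  npop <- ncol(m)
  if (npop == 1L) {
    warning("single population: private richness equals allelic richness")
    return(stats::setNames(rarefied_allelic_richness(m[, 1L], g),
                           colnames(m)))
  }
  Ntot <- colSums(m)
  if (any(g > Ntot))
    stop("g = ", g, " exceeds gene copies in population(s) ",
         paste(colnames(m)[g > Ntot], collapse = ", "))
  # Qj(i) = P(allele i present in pop j's rarefied sample)
  pres <- matrix(0, nrow(m), npop, dimnames = dimnames(m))
  for (j in seq_len(npop)) {
    absent <- exp(lchoose(Ntot[j] - m[, j], g) - lchoose(Ntot[j], g))
    absent[Ntot[j] - m[, j] < g] <- 0
    pres[, j] <- 1 - absent
  }
  out <- numeric(npop)
  for (j in seq_len(npop)) {
    others <- pres[, -j, drop = FALSE]
    out[j] <- sum(pres[, j] * apply(1 - others, 1L, prod))
  }
  stats::setNames(out, colnames(m))
}

#' Per-population diversity summary
#'
#' Mean alleles per locus, effective alleles, observed/expected/unbiased
#' expected heterozygosity, rarefied allelic richness and private allele
#' richness (at `g` gene copies), and the within-population inbreeding
#' coefficient FIS (Weir-Cockerham within-population estimator), with an
#' optional permutation p-value.
#'
#' @param dataset a [genotype_dataset()].
#' @param g rarefaction size in gene copies (default 16, i.e. 8 diploid
#'   individuals).
#' @param n_perm permutations for the FIS test per population (0 = skip).
#' @param seed seed for the permutation test.
#' @return data.frame, one row per population: `pop`, `n`, `A`, `Ae`,
#'   `Ho`, `HE`, `UHE`, `Rs`, `PAR`, `FIS`, `FIS_p` (NA when `n_perm` is
#'   0).
#' @export
population_diversity <- function(dataset, g = 16L, n_perm = 0L, seed = NULL) {
  pops <- dataset$populations
  nloc <- n_loci(dataset)
  # per locus: counts by pop, plus per-pop typed-individual and het counts
  counts <- vector("list", nloc)
  typed <- het <- matrix(0, nloc, length(pops),
                         dimnames = list(NULL, pops))
  for (j in seq_len(nloc)) {
    counts[[j]] <- allele_counts(dataset, j, by_pop = TRUE)
    m <- locus_alleles(dataset, j)
    keep <- !is.na(m[, 1L])
    popf <- factor(dataset$pop[keep], levels = pops)
    typed[j, ] <- as.integer(table(popf))
    het[j, ] <- as.integer(table(popf[m[keep, 1L] != m[keep, 2L]]))
  }
  out <- data.frame(pop = pops, n = NA_integer_, A = NA_real_,
                    Ae = NA_real_, Ho = NA_real_, HE = NA_real_,
                    UHE = NA_real_, Rs = NA_real_, PAR = NA_real_,
                    FIS = NA_real_, FIS_p = NA_real_)
  par_by_locus <- matrix(NA_real_, nloc, length(pops))
  for (j in seq_len(nloc)) {
    cj <- counts[[j]]
    if (all(2L * typed[j, ] >= g) && nrow(cj) > 0L)
      par_by_locus[j, ] <- suppressWarnings(rarefied_private_richness(cj, g))
  }
  for (i in seq_along(pops)) {
    p <- pops[i]
    out$n[i] <- sum(dataset$pop == p)
    Aj <- Aej <- Hoj <- HEj <- UHEj <- Rsj <- rep(NA_real_, nloc)
    for (j in seq_len(nloc)) {
      nj <- typed[j, i]
      if (nj == 0L) next
      cnt <- counts[[j]][, i]
      cnt <- cnt[cnt > 0]
      pfreq <- cnt / sum(cnt)
      Aj[j] <- length(cnt)
      Aej[j] <- 1 / sum(pfreq^2)
      Hoj[j] <- het[j, i] / nj
      HEj[j] <- 1 - sum(pfreq^2)
      UHEj[j] <- (2 * nj / (2 * nj - 1)) * HEj[j]
      if (2L * nj >= g) Rsj[j] <- rarefied_allelic_richness(cnt, g)
    }
    if (all(is.na(Rsj)))
      warning("population ", p, " below rarefaction size at all loci; ",
              "Rs undefined")
    out$A[i] <- mean(Aj, na.rm = TRUE)
    out$Ae[i] <- mean(Aej, na.rm = TRUE)
    out$Ho[i] <- mean(Hoj, na.rm = TRUE)
    out$HE[i] <- mean(HEj, na.rm = TRUE)
    out$UHE[i] <- mean(UHEj, na.rm = TRUE)
    out$Rs[i] <- if (all(is.na(Rsj))) NA_real_ else mean(Rsj, na.rm = TRUE)
    out$PAR[i] <- if (all(is.na(par_by_locus[, i]))) NA_real_
                  else mean(par_by_locus[, i], na.rm = TRUE)
    fis <- population_fis(dataset, p)
    out$FIS[i] <- fis
    if (n_perm > 0L) {
      out$FIS_p[i] <- fis_permutation_test(dataset, p, n_perm = n_perm,
                                           seed = seed)$p_excess
    }
  }
  out
}

# WC within-population inbreeding estimator for one population:
# f = 1 - sum(c) / sum(b + c) over alleles and loci, with r = 1
population_fis <- function(dataset, population) {
  sub <- subset_populations(dataset, population)
  fis_from_matrix(sub$alleles, n_loci(sub))
}

fis_from_matrix <- function(alleles, nloc) {
  B <- C <- 0
  for (j in seq_len(nloc)) {
    cols <- locus_cols(j)
    a1 <- alleles[, cols[1L]]; a2 <- alleles[, cols[2L]]
    keep <- !is.na(a1)
    n <- sum(keep)
    if (n < 2L) next
    a1 <- a1[keep]; a2 <- a2[keep]
    av <- sort(unique(c(a1, a2)))
    if (length(av) < 2L) next
    cnt <- tabulate(match(c(a1, a2), av), length(av))
    p <- cnt / (2 * n)
    het <- a1 != a2
    hbar <- (tabulate(match(a1[het], av), length(av)) +
               tabulate(match(a2[het], av), length(av))) / n
    b <- (n / (n - 1)) * (p * (1 - p) - ((2 * n - 1) / (4 * n)) * hbar)
    cc <- hbar / 2
    B <- B + sum(b); C <- C + sum(cc)
  }
  if (B + C <= 0) return(NA_real_)
  1 - C / (B + C)
}

#' Permutation test for the within-population inbreeding coefficient
#'
#' The null distribution is built by shuffling gene copies among
#' individuals within the population, independently per locus, which
#' destroys any within-individual allele correlation while preserving
#' allele frequencies.
#'
#' @param dataset a [genotype_dataset()].
#' @param population population ID.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional seed.
#' @return list with `fis`, `p_two` (fraction of permuted |FIS| at or
#'   above the observed |FIS|) and `p_excess` (one-tailed, homozygote
#'   excess), both with the +1 continuity convention.
#' @export
fis_permutation_test <- function(dataset, population, n_perm = 1000L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 100L) warning("n_perm below 100 gives a coarse p-value")
  sub <- subset_populations(dataset, population)
  if (n_individuals(sub) < 5L)
    stop("population ", population, " has fewer than 5 individuals")
  obs <- population_fis(dataset, population)
  nloc <- n_loci(sub)
  ge_two <- ge_one <- 0L
  for (b in seq_len(n_perm)) {
    pa <- sub$alleles
    for (j in seq_len(nloc)) {
      cols <- locus_cols(j)
      m <- pa[, cols]
      keep <- !is.na(m[, 1L])
      copies <- sample(c(m[keep, 1L], m[keep, 2L]))
      k <- sum(keep)
      m[keep, 1L] <- copies[seq_len(k)]
      m[keep, 2L] <- copies[k + seq_len(k)]
      pa[, cols] <- m
    }
    f <- fis_from_matrix(pa, nloc)
    if (!is.na(f)) {
      if (abs(f) >= abs(obs)) ge_two <- ge_two + 1L
      if (f >= obs) ge_one <- ge_one + 1L
    }
  }
  list(fis = obs,
       p_two = (ge_two + 1L) / (n_perm + 1L),
       p_excess = (ge_one + 1L) / (n_perm + 1L))
}

#' EM estimate of the null-allele frequency at a locus
#'
#' Assumes Hardy-Weinberg proportions with one unobservable (null) allele:
#' apparent homozygotes are a mixture of true homozygotes and
#' visible/null heterozygotes, and missing genotypes are null
#' homozygotes.
#'
#' @param dataset a [genotype_dataset()].
#' @param locus locus name or index.
#' @param population population ID (or `NULL` to pool all individuals).
#' @param tol convergence tolerance on the null frequency.
#' @param max_iter iteration cap; non-convergence returns the last
#'   iterate with `converged = FALSE`.
#' @return list with `r` (null-allele frequency), `freqs` (visible allele
#'   frequencies) and `converged`.
#' @export
null_allele_em <- function(dataset, locus, population = NULL,
                           tol = 1e-8, max_iter = 1000L) {
  ds <- if (is.null(population)) dataset else
    subset_populations(dataset, population)
  m <- locus_alleles(ds, locus)
  miss <- is.na(m[, 1L])
  N <- nrow(m)
  if (all(miss)) stop("all genotypes missing at this locus")
  if (N < 20L) warning("fewer than 20 genotypes; estimate will be noisy")
  a1 <- m[!miss, 1L]; a2 <- m[!miss, 2L]
  alleles <- sort(unique(c(a1, a2)))
  K <- length(alleles)
  n0 <- sum(miss)
  homo <- a1 == a2
  n_hom <- vapply(alleles, function(a) sum(homo & a1 == a), numeric(1))
  # heterozygote allele copy counts
  n_het_cop <- vapply(alleles, function(a)
    sum(!homo & a1 == a) + sum(!homo & a2 == a), numeric(1))
  # init: naive visible freqs, small null freq
  r <- if (n0 > 0) sqrt(n0 / N) else 0.05
  p <- (2 * n_hom + n_het_cop) / (2 * sum(!miss))
  p <- p * (1 - r)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E step: split apparent homozygotes of allele a into (a,a) vs (a,null)
    w_true <- ifelse(p + 2 * r > 0, p / (p + 2 * r), 1)
    exp_a <- n_het_cop + n_hom * w_true * 2 + n_hom * (1 - w_true) * 1
    exp_null <- sum(n_hom * (1 - w_true)) + 2 * n0
    tot <- sum(exp_a) + exp_null
    p_new <- exp_a / tot
    r_new <- exp_null / tot
    delta <- abs(r_new - r)
    p <- p_new; r <- r_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(r = r, freqs = stats::setNames(p, alleles), converged = converged)
}

#' Regression of within-population diversity on geography
#'
#' Ordinary least-squares regression of allelic richness and unbiased
#' expected heterozygosity on latitude, longitude and elevation (six
#' tests), with Holm's sequential Bonferroni adjustment across the six.
#'
#' @param summary output of [population_diversity()].
#' @param metadata data.frame from [read_population_table()].
#' @return data.frame with `response`, `predictor`, `slope`, `r`,
#'   `p_raw`, `p_adj`.
#' @export
geo_regression <- function(summary, metadata) {
  df <- merge(summary, metadata, by.x = "pop", by.y = "id")
  if (nrow(df) < 10L) stop("need at least 10 populations")
  responses <- c("Rs", "UHE")
  predictors <- c("lat", "lon", "elev")
  out <- expand.grid(response = responses, predictor = predictors,
                     stringsAsFactors = FALSE)
  out$slope <- out$r <- out$p_raw <- NA_real_
  for (i in seq_len(nrow(out))) {
    y <- df[[out$response[i]]]; x <- df[[out$predictor[i]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0) {
      warning("constant or missing predictor: ", out$predictor[i])
      next
    }
    fit <- stats::lm(y[ok] ~ x[ok])
    sm <- summary(fit)
    out$slope[i] <- stats::coef(fit)[2L]
    out$r[i] <- stats::cor(x[ok], y[ok])
    out$p_raw[i] <- sm$coefficients[2L, 4L]
  }
  out$p_adj <- stats::p.adjust(out$p_raw, method = "holm")
  out
}
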