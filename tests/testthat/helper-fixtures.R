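# fixture builders and independent oracles used across the suite

# small hand-built dataset: 2 pops x 2 loci
toy_dataset <- function() {
  alleles <- rbind(
    c(100L, 102L, 200L, 200L),
    c(100L, 100L, 200L, 204L),
    c(102L, 102L, 204L, 204L),
    c(104L, 102L, 200L, 204L))
  genotype_dataset(alleles, c("A", "A", "B", "B"),
                   loci = data.frame(name = c("L1", "L2"), motif = 2L))
}

# random valid dataset for round-trip / property tests
random_dataset <- function(seed, n_pops = NULL, n_loci = NULL,
                           max_ind = 6L) {
  set.seed(seed)
  if (is.null(n_pops)) n_pops <- sample(1:4, 1L)
  if (is.null(n_loci)) n_loci <- sample(1:5, 1L)
  motif <- sample(c(2L, 3L, 4L), n_loci, replace = TRUE)
  sizes <- sample(1:max_ind, n_pops, replace = TRUE)
  n <- sum(sizes)
  alleles <- matrix(NA_integer_, n, 2L * n_loci)
  for (j in seq_len(n_loci)) {
    base <- sample(80:140, 1L) * motif[j]
    ladder <- base + motif[j] * (0:6)
    g <- matrix(sample(ladder, 2L * n, replace = TRUE), ncol = 2L)
    miss <- runif(n) < 0.1
    g[miss, ] <- NA_integer_
    alleles[, 2L * j - 1L] <- g[, 1L]
    alleles[, 2L * j] <- g[, 2L]
  }
  # at least one typed genotype per locus
  for (j in seq_len(n_loci)) {
    if (all(is.na(alleles[, 2L * j - 1L]))) {
      base <- sample(80:140, 1L) * motif[j]
      alleles[1L, c(2L * j - 1L, 2L * j)] <- base
    }
  }
  pops <- paste0("pop", seq_len(n_pops))
  genotype_dataset(alleles, rep(pops, times = sizes),
                   loci = data.frame(name = paste0("L", seq_len(n_loci)),
                                     motif = motif),
                   populations = pops)
}

# HWE dataset from explicit per-population allele frequencies
hwe_dataset <- function(freq_by_pop, n_per_pop, sizes_bp, motif = 2L,
                        seed = 1L) {
  set.seed(seed)
  pops <- names(freq_by_pop)
  n <- n_per_pop * length(pops)
  alleles <- matrix(NA_integer_, n, 2L)
  row <- 0L
  for (p in pops) {
    g <- sample(sizes_bp, 2L * n_per_pop, replace = TRUE,
                prob = freq_by_pop[[p]])
    alleles[row + seq_len(n_per_pop), ] <- matrix(g, ncol = 2L)
    row <- row + n_per_pop
  }
  genotype_dataset(alleles, rep(pops, each = n_per_pop),
                   loci = data.frame(name = "L1", motif = motif),
                   populations = pops)
}

# one population, no missing data, moderate sample: for duplication tests
large_one_pop <- function(seed, n = 40L, n_loci = 4L) {
  set.seed(seed)
  alleles <- matrix(NA_integer_, n, 2L * n_loci)
  for (j in seq_len(n_loci)) {
    ladder <- (100L + 0:4) * 2L
    freqs <- rexp(5); freqs <- freqs / sum(freqs)
    g <- sample(ladder, 2L * n, replace = TRUE, prob = freqs)
    alleles[, 2L * j - 1L] <- g[seq_len(n)]
    alleles[, 2L * j] <- g[n + seq_len(n)]
  }
  genotype_dataset(alleles, rep("X", n),
                   loci = data.frame(name = paste0("L", seq_len(n_loci)),
                                     motif = 2L))
}

# write a minimal STRUCTURE _f output file; returns the path
write_structure_fixture <- function(path, lnprob, Q, labels = NULL) {
  if (is.null(labels)) labels <- paste0("ind", seq_len(nrow(Q)))
  lines <- c(
    "STRUCTURE by Pritchard, Stephens and Donnelly",
    sprintf("Estimated Ln Prob of Data   = %.1f", lnprob),
    "Mean value of ln likelihood = -999.9",
    "",
    "Inferred ancestry of individuals:",
    "        Label (%Miss) :  Inferred clusters")
  for (i in seq_len(nrow(Q))) {
    lines <- c(lines, sprintf("%3d %10s    (0)   :  %s", i, labels[i],
                              paste(sprintf("%.3f", Q[i, ]),
                                    collapse = " ")))
  }
  lines <- c(lines, "", "Estimated Allele Frequencies in each cluster")
  writeLines(lines, path)
  path
}

# ---- independent oracles ------------------------------------------------

# WC84 variance components transcribed literally from the published
# equations, one allele at a time, plain loops
wc84_oracle <- function(ds) {
  suma <- sumb <- sumc <- 0
  for (j in seq_len(n_loci(ds))) {
    m <- locus_alleles(ds, j)
    keep <- !is.na(m[, 1L])
    pops <- ds$populations
    ni <- sapply(pops, function(p) sum(keep & ds$pop == p))
    use <- ni >= 1
    pops <- pops[use]; ni <- ni[use]
    r <- length(pops)
    if (r < 2) next
    allel <- sort(unique(c(m[keep, 1L], m[keep, 2L])))
    if (length(allel) < 2) next
    nbar <- mean(ni)
    CV <- sum((ni - nbar)^2) / ((r - 1) * nbar^2) # not used; kept literal
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    for (a in allel) {
      pi <- hi <- numeric(r)
      for (ip in seq_len(r)) {
        rows <- which(keep & ds$pop == pops[ip])
        a1 <- m[rows, 1L]; a2 <- m[rows, 2L]
        pi[ip] <- (sum(a1 == a) + sum(a2 == a)) / (2 * ni[ip])
        hi[ip] <- sum(a1 != a2 & (a1 == a | a2 == a)) / ni[ip]
      }
      pbar <- sum(ni * pi) / (r * nbar)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / (r * nbar)
      a_ <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
      b_ <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
        ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
      c_ <- hbar / 2
      suma <- suma + a_; sumb <- sumb + b_; sumc <- sumc + c_
    }
  }
  c(f = 1 - sumc / (sumb + sumc), F = 1 - sumc / (suma + sumb + sumc),
    theta = suma / (suma + sumb + sumc))
}

# exhaustive-enumeration rarefaction oracle (all subsets of g copies)
rarefaction_oracle <- function(counts, g) {
  copies <- rep(seq_along(counts), times = counts)
  subsets <- utils::combn(length(copies), g)
  mean(apply(subsets, 2L, function(ix) length(unique(copies[ix]))))
}

# exhaustive private-allele oracle for two populations at subsample g
private_oracle <- function(counts_by_pop, g) {
  npop <- ncol(counts_by_pop)
  pres_prob <- function(cnts, g) {
    copies <- rep(seq_along(cnts), times = cnts)
    subsets <- utils::combn(length(copies), g)
    sapply(seq_along(cnts), function(a)
      mean(apply(subsets, 2L, function(ix) a %in% copies[ix])))
  }
  P <- sapply(seq_len(npop), function(j) pres_prob(counts_by_pop[, j], g))
  sapply(seq_len(npop), function(j) {
    others <- P[, -j, drop = FALSE]
    sum(P[, j] * apply(1 - others, 1L, prod))
  })
}

# literal Nei (1978) unbiased distance for two populations
nei_oracle <- function(x_freqs, y_freqs, nx, ny) {
  jx <- mean(sapply(seq_along(x_freqs), function(l)
    (2 * nx * sum(x_freqs[[l]]^2) - 1) / (2 * nx - 1)))
  jy <- mean(sapply(seq_along(y_freqs), function(l)
    (2 * ny * sum(y_freqs[[l]]^2) - 1) / (2 * ny - 1)))
  jxy <- mean(sapply(seq_along(x_freqs), function(l)
    sum(x_freqs[[l]] * y_freqs[[l]])))
  -log(jxy / sqrt(jx * jy))
}

# literal Jost D oracle from per-population frequencies and sizes
jost_oracle <- function(p_by_pop, n_by_pop) {
  npop <- ncol(p_by_pop)
  ntilde <- npop / sum(1 / n_by_pop)
  hs_obs <- 1 - mean(colSums(p_by_pop^2))
  hs <- (2 * ntilde / (2 * ntilde - 1)) * hs_obs
  pbar <- rowMeans(p_by_pop)
  ht <- 1 - sum(pbar^2) + hs / (2 * ntilde * npop)
  (npop / (npop - 1)) * (ht - hs) / (1 - hs)
}

# exact one-sample signed-rank distribution by enumeration of sign flips
signed_rank_exact_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  W_all <- as.matrix(signs) %*% rk
  if (alternative == "greater") mean(W_all >= W_obs) else
    mean(W_all <= W_obs)
}

# brute-force IDW at probe coordinates
idw_oracle <- function(points, px, py, power) {
  sapply(seq_along(px), function(i) {
    d <- sqrt((points$x - px[i])^2 + (points$y - py[i])^2)
    if (any(d < 1e-9)) return(points$value[which(d < 1e-9)[1L]])
    w <- d^(-power)
    sum(w * points$value) / sum(w)
  })
}
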