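test_that("locus summary matches closed forms", {
  # biallelic p = q = 0.5 -> Ae = 2, HE = 0.5, PIC = 0.375
  alleles <- matrix(rep(c(100L, 102L), 50L), ncol = 2L, byrow = TRUE)
  ds <- genotype_dataset(alleles, rep("A", 50L),
                         loci = data.frame(name = "L1", motif = 2L))
  ls <- locus_summary(ds)
  expect_equal(ls$A, 2L)
  expect_equal(ls$Ae, 2)
  expect_equal(ls$HE, 0.5)
  expect_equal(ls$PIC, 0.375)
  expect_equal(ls$Ho, 1)

  mono <- genotype_dataset(matrix(100L, 4L, 2L), rep("A", 4L),
                           loci = data.frame(name = "L1", motif = 2L))
  lm_ <- locus_summary(mono)
  expect_equal(lm_$A, 1L)
  expect_equal(lm_$Ae, 1)
  expect_equal(lm_$HE, 0)
  expect_equal(lm_$PIC, 0)
})

test_that("rarefied allelic richness equals exhaustive enumeration", {
  # printed example: counts (15, 1), g = 2 -> 1.125
  expect_equal(rarefied_allelic_richness(c(15, 1), 2), 1.125)
  expect_equal(rarefied_allelic_richness(c(16), 5), 1)
  # identity at full depth
  expect_equal(rarefied_allelic_richness(c(5, 3, 2), 10), 3)
  # exhaustive enumeration for random small instances
  set.seed(42)
  for (i in 1:20) {
    counts <- sample(1:5, sample(2:4, 1L), replace = TRUE)
    g <- sample(seq_len(sum(counts)), 1L)
    expect_equal(rarefied_allelic_richness(counts, g),
                 rarefaction_oracle(counts, g), tolerance = 1e-12)
  }
  expect_error(rarefied_allelic_richness(c(3, 2), 6), "exceeds")
})

test_that("rarefaction is monotone in g and bounded", {
  set.seed(7)
  for (i in 1:20) {
    counts <- sample(1:8, sample(2:6, 1L), replace = TRUE)
    N <- sum(counts)
    rs <- vapply(seq_len(N), function(g)
      rarefied_allelic_richness(counts, g), numeric(1))
    expect_true(all(diff(rs) >= -1e-12))
    expect_true(rs[min(2, N)] >= 1 && rs[min(2, N)] <= 2)
    expect_equal(rs[N], length(counts))
  }
})

test_that("private allelic richness matches enumeration and bounds", {
  # allele private to pop j at full count, g = Nj -> contributes exactly 1
  cb <- cbind(A = c(4, 0), B = c(2, 2))
  rownames(cb) <- c("a1", "a2")
  par4 <- rarefied_private_richness(cb, 4)
  expect_equal(unname(par4["B"]), 1)  # a2 certainly drawn, absent from A

  set.seed(11)
  for (i in 1:10) {
    cb <- matrix(sample(0:4, 6, replace = TRUE), 3L, 2L)
    cb[1L, ] <- cb[1L, ] + 1L  # keep both pops non-empty
    if (any(colSums(cb) < 2)) next
    par <- rarefied_private_richness(cb, 2)
    expect_equal(unname(par), private_oracle(cb, 2), tolerance = 1e-12)
    # PAR bounded by Rs
    for (j in 1:2) {
      rs <- rarefied_allelic_richness(cb[, j], 2)
      expect_lte(par[j], rs + 1e-12)
    }
  }
})

test_that("two identical populations share no private richness at full depth", {
  cb <- cbind(A = c(3, 3), B = c(3, 3))
  par <- rarefied_private_richness(cb, 6)
  expect_equal(unname(par), c(0, 0))
})

test_that("population diversity reproduces hand-computed values", {
  # N = 10, p = (0.5, 0.5): UHE = (20/19) * 0.5
  alleles <- matrix(rep(c(100L, 102L), 10L), ncol = 2L, byrow = TRUE)
  ds <- genotype_dataset(alleles, rep("A", 10L),
                         loci = data.frame(name = "L1", motif = 2L))
  pd <- population_diversity(ds, g = 4L)
  expect_equal(pd$UHE, (20 / 19) * 0.5)
  expect_equal(pd$HE, 0.5)
  expect_equal(pd$Ho, 1)

  # rarefaction at the full sample depth returns the observed count
  pd_full <- population_diversity(ds, g = 20L)
  expect_equal(pd_full$Rs, 2)
})

test_that("duplicated populations give identical summary rows", {
  ds <- random_dataset(5, n_pops = 1L, n_loci = 3L, max_ind = 8L)
  dup <- genotype_dataset(rbind(ds$alleles, ds$alleles),
                          c(rep("X", n_individuals(ds)),
                            rep("Y", n_individuals(ds))),
                          loci = ds$loci, populations = c("X", "Y"))
  pd <- population_diversity(dup, g = 2L)
  expect_equal(unlist(pd[1L, -1L]), unlist(pd[2L, -1L]))
})

test_that("null-allele EM recovers an injected null frequency", {
  cfg <- island_config(1, 400, n_loci = 1, theta = 5, migration = 0,
                       P = 0, seed = 21)
  ds <- generate_island_dataset(cfg)
  em0 <- null_allele_em(ds, 1L)
  expect_lt(abs(em0$r), 0.02)

  withnull <- inject_null_alleles(ds, 1L, 0.2, seed = 9)
  em <- null_allele_em(withnull, 1L)
  expect_true(em$converged)
  expect_lt(abs(em$r - 0.2), 0.03)

  # null_freq = 0 leaves the dataset untouched
  expect_true(datasets_equal(ds, inject_null_alleles(ds, 1L, 0)))
  # all-missing locus errors
  allmiss <- ds
  allmiss$alleles[] <- NA_integer_
  expect_error(null_allele_em(allmiss, 1L), "missing")
})

test_that("null injection at 0.5 leaves about a quarter missing", {
  cfg <- island_config(1, 400, n_loci = 1, theta = 5, migration = 0,
                       P = 0, seed = 3)
  ds <- generate_island_dataset(cfg)
  wn <- inject_null_alleles(ds, 1L, 0.5, seed = 5)
  frac_missing <- mean(is.na(locus_alleles(wn, 1L)[, 1L]))
  expect_lt(abs(frac_missing - 0.25), 0.05)
})

test_that("FIS permutation test flags selfed populations", {
  # all homozygotes at two alleles: FIS = 1
  alleles <- cbind(rep(c(100L, 102L), 10L), rep(c(100L, 102L), 10L))
  ds <- genotype_dataset(alleles, rep("A", 20L),
                         loci = data.frame(name = "L1", motif = 2L))
  res <- fis_permutation_test(ds, "A", n_perm = 199L, seed = 1)
  expect_equal(res$fis, 1)
  expect_lte(res$p_excess, 1 / 200)
})

test_that("FIS permutation p-values are roughly uniform under HWE", {
  set.seed(99)
  nfix <- 120L
  pvals <- numeric(nfix)
  for (i in seq_len(nfix)) {
    ds <- generate_island_dataset(
      island_config(1, 30, n_loci = 4, theta = 3, migration = 0, P = 0,
                    seed = 1000 + i))
    pvals[i] <- fis_permutation_test(ds, "pop_1", n_perm = 199L,
                                     seed = i)$p_excess
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pvals) - 0.5), 0.1)
})

test_that("geography regression finds the built-in gradient and controls FWER", {
  fx <- study_shape_fixture(seed = 4)
  pd <- population_diversity(fx$dataset, g = 16L)
  gr <- geo_regression(pd, fx$metadata)
  lon_rs <- gr[gr$response == "Rs" & gr$predictor == "lon", ]
  expect_gt(lon_rs$slope, 0)
  expect_lt(lon_rs$p_adj, 0.05)

  # permuted responses: familywise error rate of the Holm adjustment
  set.seed(123)
  md <- fx$metadata
  n_rep <- 200L
  any_sig <- logical(n_rep)
  for (b in seq_len(n_rep)) {
    perm <- pd
    perm[, c("Rs", "UHE")] <- pd[sample(nrow(pd)), c("Rs", "UHE")]
    g <- geo_regression(perm, md)
    any_sig[b] <- any(g$p_adj < 0.05, na.rm = TRUE)
  }
  expect_lte(mean(any_sig), 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})
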