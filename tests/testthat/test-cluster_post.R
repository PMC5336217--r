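test_that("Evanno's deltaK reproduces the hand-computed second difference", {
  runs <- expand.grid(rep = 1:2, K = 1:4)
  means <- c(-100, -50, -45, -44)
  # two runs per K straddling the mean by +/- off so that sd(L) = 1
  off <- 0.5 * sqrt(2)
  runs$lnprob <- means[runs$K] + ifelse(runs$rep == 1, off, -off)
  ev <- evanno(runs[, c("K", "lnprob")])
  # deltaK(2) = |-45 + 100 - 2*(-50)... i.e. |L(3) - 2 L(2) + L(1)| / 1
  expect_equal(ev$table$d2, c(NA, 45, 4, NA))
  expect_equal(ev$table$deltaK, c(NA, 45, 4, NA))
  expect_equal(ev$best_K, 2L)

  # linear L in K -> zero second differences at interior points
  lin <- expand.grid(rep = 1:2, K = 1:5)
  lin$lnprob <- -10 * lin$K + ifelse(lin$rep == 1, 0.3, -0.3)
  evl <- evanno(lin[, c("K", "lnprob")])
  expect_equal(evl$table$d2[2:4], rep(0, 3L))
})

test_that("run alignment recovers permuted columns exactly", {
  set.seed(2)
  Q <- matrix(runif(40), 10L)
  Q <- Q / rowSums(Q)
  perm <- c(3L, 1L, 4L, 2L)
  avg <- align_runs(list(Q, Q[, perm]))
  expect_equal(avg, Q, tolerance = 1e-12)

  # noisy replicates: average stays within the noise level of truth
  eps <- 0.01
  runs <- lapply(1:6, function(i) {
    noise <- matrix(runif(40, -eps, eps), 10L)
    qi <- pmax(Q + noise, 1e-6)
    qi <- qi / rowSums(qi)
    if (i > 1) qi <- qi[, sample(4L)]  # reference run keeps truth's order
    qi
  })
  avg6 <- align_runs(runs)
  expect_lt(max(abs(avg6 - Q)), 2 * eps)

  expect_error(align_runs(list(matrix(1 / 9, 3L, 9L),
                               matrix(1 / 9, 3L, 9L))), "K <= 8")
})

test_that("alignment is invariant to permuting any run's columns", {
  set.seed(8)
  Q1 <- matrix(runif(20), 5L); Q1 <- Q1 / rowSums(Q1)
  Q2 <- matrix(runif(20), 5L); Q2 <- Q2 / rowSums(Q2)
  base <- align_runs(list(Q1, Q2))
  for (i in 1:5) {
    expect_equal(align_runs(list(Q1, Q2[, sample(4L)])), base,
                 tolerance = 1e-12)
  }
})

test_that("membership classification follows the threshold rule", {
  q <- rbind(c(0.80, 0.10, 0.05, 0.05),
             c(0.50, 0.50, 0.00, 0.00),
             c(0.74, 0.26, 0.00, 0.00),
             c(0.75, 0.25, 0.00, 0.00))
  got <- classify_membership(q, 0.75)
  expect_equal(got, c("1", "admixed", "admixed", "1"))
  # threshold 1.0 assigns only certainty
  expect_equal(classify_membership(rbind(c(1, 0), c(0.99, 0.01)), 1),
               c("1", "admixed"))
  expect_error(classify_membership(q, 0.5), "threshold")
})

test_that("IDW interpolation matches a brute-force evaluation", {
  pts <- data.frame(x = c(0, 10, 5), y = c(0, 0, 8),
                    value = c(1, 3, 10))
  grid <- raster_grid(0, 0, 1, 10L, 10L)
  surf <- idw_surface(pts, grid, power = 2)
  cc <- walnutpg:::cell_centres(grid)
  for (probe in list(c(2, 3), c(9, 9), c(5, 5), c(1, 10), c(10, 1),
                     c(4, 4), c(7, 2), c(2, 8), c(6, 9), c(3, 1))) {
    r <- probe[1L]; cl <- probe[2L]
    want <- idw_oracle(pts, cc$x[cl], cc$y[r], 2)
    expect_equal(surf$bands[[1L]][r, cl], want, tolerance = 1e-12)
  }
  # convex combination: surface within data range
  expect_true(all(surf$bands[[1L]] >= min(pts$value) - 1e-12))
  expect_true(all(surf$bands[[1L]] <= max(pts$value) + 1e-12))
})

test_that("IDW reproduces data values at data points and handles symmetry", {
  # single point -> constant surface
  one <- data.frame(x = 2, y = 2, value = 7)
  g <- raster_grid(0, 0, 1, 4L, 4L)
  expect_true(all(idw_surface(one, g)$bands[[1L]] == 7))

  # midpoint of two points -> arithmetic mean for any power
  pts <- data.frame(x = c(0.5, 4.5), y = c(2.5, 2.5), value = c(2, 8))
  g5 <- raster_grid(0, 0, 1, 5L, 5L)
  for (p in c(1, 2, 4)) {
    surf <- idw_surface(pts, g5, power = p)
    expect_equal(surf$bands[[1L]][3L, 3L], 5)
  }
  # a cell centred on a data point returns the point value exactly
  expect_equal(idw_surface(pts, g5, power = 2)$bands[[1L]][3L, 1L], 2)

  dup <- data.frame(x = c(1, 1), y = c(1, 1), value = c(1, 2))
  expect_error(idw_surface(dup, g5), "coincident")
})

test_that("composite maps mix cluster colours within [0, 1]", {
  g <- raster_grid(0, 0, 1, 3L, 3L)
  ones <- raster_grid(0, 0, 1, 3L, 3L,
                      bands = list(matrix(1, 3L, 3L)))
  zero <- raster_grid(0, 0, 1, 3L, 3L,
                      bands = list(matrix(0, 3L, 3L)))
  comp <- composite_map(list(ones, zero),
                        colors = rbind(c(1, 0, 0), c(0, 0, 1)))
  expect_equal(comp$bands[[1L]][1L, 1L], 1)
  expect_equal(comp$bands[[3L]][1L, 1L], 0)

  half <- raster_grid(0, 0, 1, 3L, 3L,
                      bands = list(matrix(0.5, 3L, 3L)))
  mid <- composite_map(list(half, half),
                       colors = rbind(c(1, 0, 0), c(0, 0, 1)))
  expect_equal(mid$bands[[1L]][2L, 2L], 0.5)
  expect_equal(mid$bands[[3L]][2L, 2L], 0.5)

  set.seed(3)
  rnd <- lapply(1:3, function(i)
    raster_grid(0, 0, 1, 3L, 3L,
                bands = list(matrix(runif(9, 0, 0.6), 3L, 3L))))
  cm <- composite_map(rnd)
  for (b in cm$bands) {
    expect_true(all(b >= 0 & b <= 1))
  }

  other <- raster_grid(0, 0, 2, 3L, 3L)
  expect_error(composite_map(list(ones, other)), "common grid")
})

test_that("ASCII grid export is well-formed", {
  g <- raster_grid(10, 20, 0.5, 2L, 3L,
                   bands = list(matrix(1:6, 2L, 3L)))
  f <- tempfile(fileext = ".asc")
  on.exit(unlink(f))
  write_ascii_grid(g, f)
  txt <- readLines(f)
  expect_equal(txt[1L], "ncols 3")
  expect_equal(txt[2L], "nrows 2")
  expect_equal(length(txt), 8L)
})
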