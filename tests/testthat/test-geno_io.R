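test_that("GenePop files are parsed correctly", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy SSR file",
               "locA", "locB",
               "pop",
               "i1 , 001002 003003",
               "i2 , 000000 003004",
               "pop",
               "i3 , 002002 004004"), f)
  ds <- read_genepop(f)
  expect_equal(n_populations(ds), 2L)
  expect_equal(n_loci(ds), 2L)
  expect_equal(sort(unique(as.vector(locus_alleles(ds, "locA")))),
               c(1L, 2L))
  # first individual: both alleles missing at locus A? no -- (1,2);
  # second individual all-zeros at locus A -> missing pair
  expect_true(all(is.na(locus_alleles(ds, "locA")[2L, ])))
  expect_false(anyNA(locus_alleles(ds, "locB")[2L, ]))
})

test_that("malformed GenePop input gives informative errors", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("bad", "locA", "pop", "i1 , 001002003"), f)
  expect_error(read_genepop(f), "width")
  writeLines(c("bad", "locA", "pop", "i1 , 0102", "i2 , 010203 "), f)
  expect_error(read_genepop(f), "line")
  writeLines(c("no pops here", "locA", "i1 , 0102"), f)
  expect_error(read_genepop(f), "pop")
  # half-missing genotype rejected
  writeLines(c("bad", "locA", "pop", "i1 , 000101"), f)
  expect_error(read_genepop(f), "half-missing")
})

test_that("write_genepop refuses empty populations and encodes genotypes", {
  ds <- toy_dataset()
  ds$populations <- c(ds$populations, "EMPTY")
  f <- withr::local_tempfile(fileext = ".gen")
  expect_error(write_genepop(ds, f), "empty")

  one <- genotype_dataset(matrix(c(101L, 103L), 1L),
                          "A", loci = data.frame(name = "L1", motif = 2L))
  write_genepop(one, f)
  txt <- readLines(f)
  expect_true(any(grepl("101103", txt)))
})

test_that("GenePop round-trip is the identity on random datasets", {
  f <- withr::local_tempfile(fileext = ".gen")
  for (seed in 1:100) {
    ds <- random_dataset(seed)
    write_genepop(ds, f)
    back <- read_genepop(f)
    expect_true(datasets_equal(ds, back),
                info = paste("seed", seed))
  }
})

test_that("round-trip preserves wide allele sizes via offsets", {
  alleles <- matrix(c(1200L, 1204L, 1202L, 1202L), 2L, byrow = TRUE)
  ds <- genotype_dataset(alleles, c("A", "A"),
                         loci = data.frame(name = "big", motif = 2L))
  f <- withr::local_tempfile(fileext = ".gen")
  write_genepop(ds, f)
  expect_true(datasets_equal(ds, read_genepop(f)))
})

test_that("allele-count bookkeeping matches typed individuals", {
  for (seed in c(3, 17, 44)) {
    ds <- random_dataset(seed)
    for (j in seq_len(n_loci(ds))) {
      cnt <- allele_counts(ds, j, by_pop = TRUE)
      m <- locus_alleles(ds, j)
      expect_equal(sum(cnt), 2L * sum(!is.na(m[, 1L])))
    }
  }
})

test_that("population metadata tables are validated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,lat,lon,elev",
               "41-PAIKO_A, 40.9, 22.3, 600",
               "42-PAIKO_B, 41.0, 22.4, 650"), f)
  md <- read_population_table(f)
  expect_equal(md$id[1L], "41-PAIKO_A")
  expect_equal(md$lat[1L], 40.9)
  expect_equal(md$elev[2L], 650)

  writeLines(c("id,lat,lon", "a, 95, 10"), f)
  expect_error(read_population_table(f), "latitude")
  writeLines(c("id,lat,lon", "a, 45, 10", "a, 46, 11"), f)
  expect_error(read_population_table(f), "duplicate")
  writeLines("id,lat,lon", f)
  expect_warning(md <- read_population_table(f), "empty")
  expect_equal(nrow(md), 0L)
})

test_that("STRUCTURE run files are parsed and validated", {
  f <- withr::local_tempfile()
  Q <- rbind(c(0.9, 0.05, 0.05), c(0.2, 0.3, 0.5))
  write_structure_fixture(f, -1234.5, Q)
  run <- read_structure_runs(f)[[1L]]
  expect_equal(run$K, 3L)
  expect_equal(run$lnprob, -1234.5)
  expect_equal(unname(run$Q[1L, ]), c(0.9, 0.05, 0.05))

  # six runs at one K all parse to the same K
  paths <- vapply(1:6, function(i) tempfile(), character(1))
  on.exit(unlink(paths), add = TRUE)
  for (i in 1:6) {
    a <- 0.1 + 0.05 * i
    Q4 <- rbind(c(a, 1 - a), c(1 - a, a))
    write_structure_fixture(paths[i], -1000 - i, Q4)
  }
  runs <- read_structure_runs(paths)
  expect_true(all(vapply(runs, function(r) r$K, integer(1)) == 2L))

  bad <- withr::local_tempfile()
  write_structure_fixture(bad, -10, rbind(c(0.5, 0.5, 0.1)))
  expect_error(read_structure_runs(bad), "sums to")
})

test_that("newick output round-trips through an independent parser", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0.5);")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_equal(sort(back$tip.label), c("A", "B", "C", "D"))
  expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE))

  two <- ape::read.tree(text = "(A:1,B:2);")
  write_newick(two, f)
  expect_match(readLines(f), "^\\(A:1,B:2\\);$")

  tr$tip.label[1L] <- ""
  expect_error(write_newick(tr, f), "labelled")
})
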