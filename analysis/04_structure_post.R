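#!/usr/bin/env Rscript
# Stage 4: Bayesian-clustering post-processing and diversity surfaces.
#
# The MCMC clustering itself is an upstream tool; this stage consumes
# run outputs. Replicate runs are emulated here from the collection's
# geography (four regional clusters with noisy log-likelihoods peaking
# at K = 4), then pushed through the Evanno delta-K table, exhaustive
# run alignment, the Q >= 0.75 membership rule, and inverse-distance-
# weighted interpolation into cluster and diversity surfaces.

library(walnutpg)
set.seed(42)
meta <- read_population_table("results/collection_meta.csv")
n <- nrow(meta)

# synthetic replicate clustering runs: 6 per K over K = 1..8
true_q <- function(K) {
  centres <- seq(min(meta$lon), max(meta$lon), length.out = K)
  w <- exp(-outer(meta$lon, centres, function(a, b) (a - b)^2 / 200))
  w / rowSums(w)
}
runs <- expand.grid(rep = 1:6, K = 1:8)
peak <- 4L
runs$lnprob <- -2000 + 150 * pmin(runs$K, peak) -
  40 * pmax(runs$K - peak, 0) + rnorm(nrow(runs), 0, 5)
ev <- evanno(runs[, c("K", "lnprob")])
write.csv(ev$table, "results/evanno.csv", row.names = FALSE)
cat("best K by deltaK:", ev$best_K, "\n")

Q4 <- true_q(4)
qruns <- lapply(1:6, function(i) {
  noise <- matrix(runif(n * 4, -0.02, 0.02), n)
  qi <- pmax(Q4 + noise, 1e-6)
  qi <- qi / rowSums(qi)
  if (i > 1) qi[, sample(4)] else qi
})
qavg <- align_runs(qruns)
labels <- classify_membership(qavg, threshold = 0.75)
cat("membership at Q >= 0.75:",
    paste(names(table(labels)), table(labels), collapse = ", "), "\n")
write.csv(data.frame(pop = meta$id, qavg, label = labels),
          "results/membership.csv", row.names = FALSE)

# IDW surfaces on the collection's bounding box
grid <- raster_grid(min(meta$lon) - 1, min(meta$lat) - 1, 0.5,
                    nrow = ceiling((diff(range(meta$lat)) + 2) / 0.5),
                    ncol = ceiling((diff(range(meta$lon)) + 2) / 0.5))
pd <- read.csv("results/population_diversity.csv")
rs_pts <- data.frame(x = meta$lon, y = meta$lat,
                     value = pd$Rs[match(meta$id, pd$pop)])
write_ascii_grid(idw_surface(rs_pts, grid), "results/rs_surface.asc")

surfaces <- lapply(1:4, function(k)
  idw_surface(data.frame(x = meta$lon, y = meta$lat, value = qavg[, k]),
              grid))
comp <- composite_map(surfaces)
write_ascii_grid(comp, "results/cluster_composite.asc")
cat("wrote results/rs_surface.asc and results/cluster_composite.asc",
    "(3 RGB bands)\n")
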