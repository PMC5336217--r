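#!/usr/bin/env Rscript
# Stage 2: diversity and differentiation statistics.
#
# Per-locus summaries over the pooled sample, per-population diversity
# with rarefied allelic and private-allele richness (8 diploid
# individuals, i.e. 16 gene copies), Weir-Cockerham F-statistics,
# Jost's D, and the regression of within-population diversity on
# geography with Holm correction.

library(walnutpg)
ds <- read_genepop("results/collection.gen")
meta <- read_population_table("results/collection_meta.csv")

ls <- locus_summary(ds)
write.csv(ls, "results/locus_summary.csv", row.names = FALSE)
cat("locus means: A =", round(attr(ls, "means")[["A"]], 2),
    "| Ae =", round(attr(ls, "means")[["Ae"]], 2),
    "| HE =", round(attr(ls, "means")[["HE"]], 3), "\n")

pd <- population_diversity(ds, g = 16L)
write.csv(pd, "results/population_diversity.csv", row.names = FALSE)
cat("population Rs range:", round(min(pd$Rs, na.rm = TRUE), 2), "-",
    round(max(pd$Rs, na.rm = TRUE), 2), "\n")

fs <- wc_fstats(ds)
write.csv(fs$per_locus, "results/fstats_per_locus.csv", row.names = FALSE)
cat("multilocus f =", round(fs$overall[["f"]], 4),
    "| F =", round(fs$overall[["F"]], 4),
    "| theta =", round(fs$overall[["theta"]], 4), "\n")

jd <- jost_d(ds)
write.csv(jd$per_locus, "results/jost_d_per_locus.csv", row.names = FALSE)
cat("Jost's D (harmonic over loci):",
    round(jd$combined[["harmonic"]], 4), "\n")

gr <- geo_regression(pd, meta)
write.csv(gr, "results/geo_regression.csv", row.names = FALSE)
sig <- gr[!is.na(gr$p_adj) & gr$p_adj < 0.05, ]
cat("significant geography effects after Holm:\n")
print(sig[, c("response", "predictor", "slope", "r", "p_adj")],
      row.names = FALSE)
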