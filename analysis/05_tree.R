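#!/usr/bin/env Rscript
# Stage 5: population tree.
#
# Nei (1978) unbiased genetic distance over all population pairs and a
# neighbor-joining tree, exported as newick.

library(walnutpg)
ds <- read_genepop("results/collection.gen")

D <- nei_unbiased_distance(ds)
flags <- attr(D, "flags")
if (length(flags)) cat("distance flags:", length(flags), "\n")
write.csv(round(D, 6), "results/nei_distance.csv")

tree <- neighbor_joining(D)
write_newick(tree, "results/nj_tree.nwk")
cat("NJ tree over", ape::Ntip(tree), "populations;",
    attr(tree, "negative_branches"), "negative branch length(s)\n")
cat("wrote results/nei_distance.csv and results/nj_tree.nwk\n")
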