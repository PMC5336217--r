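Package: walnutpg
Title: Microsatellite Phylogeography and Coalescent ABC for Walnut Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a Eurasian common walnut
    (Juglans regia) microsatellite phylogeography pipeline: GenePop and
    STRUCTURE-output I/O, per-locus and per-population diversity statistics
    (allelic richness and private allele rarefaction, Weir-Cockerham
    F-statistics, Jost's D, null-allele EM), bottleneck detection
    (two-phase-model heterozygosity excess, mode shift, M-ratio), Nei
    distance and neighbor-joining population trees, Bayesian-clustering
    post-processing (Evanno's delta-K, run alignment, membership
    classification, inverse-distance-weighted surfaces), and a
    coalescent-based approximate Bayesian computation engine with a
    generalized stepwise mutation model encoding ten demographic scenarios
    of postglacial walnut dispersal across Europe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    nnet,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
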