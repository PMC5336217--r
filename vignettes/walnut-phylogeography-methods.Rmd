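---
title: "Models and methods behind the walnut phylogeography pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the walnut phylogeography pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(walnutpg)
```

This vignette documents the models, estimators and numerical choices in
`walnutpg`, in the spirit of a methods section: what is computed, under
which assumptions, which knobs matter, and what the built-in validation
does and does not demonstrate.

## The data model

A `genotype_dataset` holds diploid allele-size calls (base pairs) for
individuals at SSR loci, with a population label per individual and a
motif length per locus. Two conventions are enforced throughout:

* a genotype is missing as a unit — a record with exactly one missing
  allele is rejected, because fragment scoring either amplifies a locus
  or it does not;
* allele sizes at a locus must sit on the motif ladder (all pairwise
  differences multiples of the motif length), unless the dataset is
  flagged `raw`. The repeat-unit conversion needed by the M-ratio and
  the mutation model is done on demand from the motif length, keeping
  file I/O lossless.

GenePop is the interchange format. The dialect written here stores the
locus motif lengths and any per-locus allele-size offsets in the title
line, so `write_genepop()` followed by `read_genepop()` is the identity
on valid datasets (a property the suite checks on 100 randomized
fixtures). Files from other programs (without that title metadata) are
read with a 2-bp motif default and flagged raw.

## Diversity estimators

Per-locus summaries pool allele frequencies over populations (the
convention of the common spreadsheet tools for S5-style tables);
per-population summaries use within-population frequencies. Unbiased
expected heterozygosity applies the `2n/(2n−1)` small-sample factor per
locus before averaging. Rarefaction uses the exact hypergeometric form

\[ Rs(g) = \sum_i \left[ 1 - \binom{N-N_i}{g} \Big/ \binom{N}{g} \right] \]

with `g = 16` gene copies (8 diploid individuals) by default, matching
the standardization of the original analysis; private allele richness
multiplies each allele's presence probability in the focal population's
rarefied sample by its absence probability in every other population's.
Both equal exhaustive subset enumeration to 1e-12 on small instances.

Weir–Cockerham variance components a, b, c are computed per allele and
locus; `f`, `F`, `θ` are ratios of summed components (never means of
per-locus ratios). Jost's D uses the Nei–Chesser-corrected within- and
total-heterozygosity with the harmonic-mean sample size; across loci the
harmonic mean of positive per-locus values is reported alongside the
arithmetic mean, since the multi-locus combination is a convention
rather than part of the estimator.

The null-allele EM treats apparent homozygotes as mixtures of true
homozygotes and visible/null heterozygotes and whole-missing genotypes
as null homozygotes, iterating allele-frequency expectations to
`|Δr| < 1e-8` (cap 1000 iterations). The F_IS permutation test shuffles
gene copies among individuals within the population per locus, which
preserves allele frequencies while destroying within-individual
correlation; p-values use the `(hits + 1)/(n + 1)` convention.

"Sequential Bonferroni" for the geography regressions is implemented as
Holm's method, its standard identification, across the six tests (Rs
and UHE against latitude, longitude, elevation).

## Bottleneck tests

The heterozygosity-excess test simulates the equilibrium distribution
of expected heterozygosity conditional on the observed allele count k:
theta is calibrated by stochastic bisection until the mean simulated
allele count matches k, then runs are rejection-retained until the
requested number carry exactly k alleles. The mutation model is the
two-phase model: 70% single-step mutations, multistep magnitudes
geometric with variance 30 (success probability 1/6, mean 6). One
numerical choice matters here: the conditional Heq distribution is
left-skewed, so differences from its **mean** are positive more than
half the time even at equilibrium (empirically P ≈ 0.59), which would
inflate the one-tailed Wilcoxon signed-rank test to a ~12% type-I rate.
The signed-rank test is therefore centred on the conditional **median**
(empirical type-I ≈ 2.5%, within the nominal band), while the reported
per-locus standardized differences remain mean/SD-based. The exact
signed-rank null is used for ≤ 25 untied loci.

The M-ratio uses M = k/(r+1) with r the allele-size range in repeat
units, averaged over polymorphic loci and compared to the fixed 0.68
threshold. The equilibrium validation simulates strict stepwise
mutation: that is the regime the 0.68 critical value was calibrated
against — under a multistep-heavy model, rare large jumps stretch the
range and deflate M even at equilibrium (mean M ≈ 0.44 under the TPM
versus ≈ 0.93 under SMM at θ = 5), so an equilibrium M check against
0.68 is only meaningful under SMM. Mode-shift ties (first frequency
class equal to the best other class) are classified "shifted",
conservative toward signalling disturbance.

## Trees and clustering post-processing

Nei's (1978) unbiased distance floors non-positive unbiased identities
at 1/(allele count) and clamps negative distances to zero, both flagged;
pairs with zero between-population identity get an infinite distance
flag and must be treated before tree building. Neighbor-joining runs
through `ape::nj` and is checked against additive matrices by exact
path-length recovery.

Evanno's ΔK is the absolute second difference of mean log-likelihoods
over replicate runs divided by their SD at each interior K. Run
alignment minimizes the summed squared difference to the first run over
all K! column permutations (K ≤ 8), equivalent to the CLUMPP full-search
objective up to a monotone transform. Membership classification applies
the Q ≥ 0.75 threshold; anything below is admixed.

IDW interpolation uses power 2 and the all-points neighbourhood (the
common GIS defaults; the original analysis does not state them), planar
Euclidean distance by default with an optional great-circle mode for
lon/lat. Cells within 1e-9 of a sample point take the point's value, so
the surface interpolates exactly and, being a convex combination, never
leaves the data range. Rasters are written as ESRI ASCII grids (one
file per band); composite maps mix a fixed cluster palette by Q-weights
and clip channels to [0, 1].

## The coalescent ABC engine

### Scenarios and priors

A scenario is a list of pools (each with a size parameter) and
backward-time events: `merge(t, source, sink)`, `admix(t, derived,
parentA, parentB, rate)` and `sizechange(t, pool, size)`. Validation
checks that every referenced parameter has a prior, admixture-rate
priors sit inside (0, 1), every pool terminates exactly once with one
final ancestor reachable from everywhere, and the ordering constraints
are acyclic. Priors are uniform or log-uniform; constraint-violating
draws are rejected and redrawn, and a sub-1/10⁴ acceptance rate is
treated as an inconsistent specification.

The eleven shipped walnut scenarios follow the published stage-1/stage-2
structure. Effective-size priors are U(100, 10 000) (the published
posterior supports sit inside this range); event-time priors map the
historical windows: last glacial U(100, 10 000), post-glacial
U(10, 200), Bronze/Iron Age U(20, 60), Hellenistic–Roman U(10, 25), and
the two medieval/recent windows U(1, 15) (td) and U(1, 10) (tm) —
assigned that way because the published 90% intervals (1–13.8 and 1–10)
fit exactly that assignment. Admixture rates are U(0.001, 0.999). In
scenario 6b the rate `rb` weights the pool4 side of the t1 admixture
that founds pool3. The stage-2 two-refugia scenarios (1b–3b) reuse the
deep time t4 for the Anatolia/western-Europe split, since t3 times the
NG1 divergence that only exists with three refugia.

### Simulation

One continuous-time coalescent kernel drives every simulator in the
package. Within a pool of diploid size N, k lineages coalesce at rate
k(k−1)/(4N) per generation; events relabel lineages (merge), split them
binomially (admixture, probability = rate toward parent A) or change
the pool size. After the last event all lineages sit in the final pool
and the kernel switches to a lean single-pool loop. Mutations are
Poisson on branch lengths with one μ per dataset, shared across loci
(drawn from U(10⁻⁴, 10⁻³)); each mutation shifts the allele by a
geometric number of repeat units (parameter P ~ U(0.1, 0.3) per
dataset), sign fair; the root sits at 100 repeat units, an arbitrary but
reproducible ladder origin, and no allele-size clamp is applied by
default (a DIYABC-style window is available via the locus model).
Diploid genotypes pair consecutive gene copies within each pool, which
is random pairing by exchangeability.

Two closed forms anchor the simulator: the pairwise squared allele-size
difference E[(ΔX)²] = θ(1+P)/(1−P)², and strict-SMM equilibrium
homozygosity 1/√(1+2θ). Both are checked to within 3 Monte-Carlo SE.

### Summary statistics, rejection, posteriors

Each dataset is summarized by, per pool, the mean allele count, mean
unbiased heterozygosity and mean allele-size variance per locus; per
unordered pool pair, the multilocus Weir–Cockerham F_ST and a
shared-allele classification index; per ordered pair (i→j), the mean
over pool-i individuals of the log₁₀ genotype likelihood under pool-j
allele frequencies, add-one smoothed over the locus's observed allele
set (36 statistics for four pools). The classification index is the
fraction of individuals closer (by mean shared-allele distance
DAS = 1 − shared/(2·loci), self excluded) to their own pool than to the
other, averaged over both directions, with exact ties credited one
half; the precise DAS-based index of the original toolchain is not
restated anywhere, so this concrete definition is declared rather than
inferred.

Statistics are normalized by their per-column median absolute deviation
over the reference table; rejection keeps the `ceiling(fraction·rows)`
smallest Euclidean distances with ties broken by row index. The direct
posterior is the scenario share among the closest rows (default 500)
with normal multinomial confidence intervals; the logistic posterior
fits `nnet::multinom` on the deviations from the observed vector and
evaluates at the origin, with delta-method intervals on the intercepts;
near-separated fits are refit with a small ridge (weight decay) and
flagged; fully separated rejections (all retained rows one scenario)
make that scenario the outright winner in `top_scenario()`.

Parameter estimation maps each parameter to the real line by a logit of
its position in the prior support, applies the Beaumont-style weighted
local-linear adjustment (Epanechnikov weights on the rejection
distances), and back-transforms, so estimates respect prior bounds by
construction. Two numerical guards matter at desk scale: when the
retained set is small relative to the 36 statistics the regression
would interpolate exactly, so the design is projected onto at most
`retained/3` leading principal components first; and rank-deficient
directions get a zero (no adjustment) coefficient. Parameters piled on
a prior bound in more than half the retained rows skip adjustment and
are flagged. Quantiles are weighted quantiles of the adjusted draws.

Model checking resamples constraint-satisfying parameter vectors from
the weighted posterior, simulates datasets, and reports per-statistic
tail probabilities, flagged outside (0.005, 0.995) — two-sided at the
1% level. Type I/II error rates rerun the full model choice on
pseudo-observed datasets simulated under the focal scenario or each
competitor.

### Determinism

One master seed drives everything; reference-table rows draw their own
RNG substream from a per-row seed generated up front, so serial runs,
reruns, and any evaluation order (the stand-in for parallel workers)
produce byte-identical tables, and downstream posteriors and rasters
inherit that reproducibility.

## The synthetic study collection

The genotype tables behind the original study are not deposited, so the
workflow and tests run on synthetic data from two generators. The
island-model generator shares the coalescent kernel (symmetric
migration, internal deme size 1000 diploids, rates derived from the
scaled θ = 4Nμ and M = 4Nm). The study-shaped fixture reproduces the
collection's *shape* — 91 populations, 2,008 diploid trees, 14
dinucleotide loci, ~200 alleles, population sizes of 8 plus a
multinomial remainder, a Eurasian-like coordinate span — and builds the
west-to-east diversity cline by scaling a Dirichlet concentration
(1.5 in the far west to 30 in the far east) around shared broken-stick
allele frequencies, with Hardy–Weinberg genotype draws. It makes no
claim to coalescent realism: there is no linkage, no isolation by
distance beyond the smooth cline, no missing data, and no admixture
structure. Tests passing on it demonstrate that the estimators recover
built-in signals, not that the biological conclusions would reproduce
on the real collection.

## Validation experiments and their problem sizes

Because the real data are unavailable, the published posterior
probabilities and error rates are not reproducible; the machinery is
validated by simulation instead, at sizes chosen to keep each
experiment in desk time while leaving the conclusions stable:

* **Scenario recovery** — three deliberately well-separated two-pool
  scenarios (long isolation; very recent split; isolation with a
  crashed second pool), 500 reference rows per scenario, 20 diploids
  per pool, 14 loci, 50 pseudo-observed datasets, 10% rejection. The
  generating scenario should win the logistic model choice in ≥ 80% of
  pods (observed: 100% in the development runs).
* **Parameter recovery** — a two-pool divergence scenario whose pools
  and ancestor share one size N, truth N = 2000, t = 50 generations,
  with the mutation model pinned at the true rate so N and t are both
  identifiable (with μ free over a decade, only θ = 4Nμ is identified
  and no size can be recovered to a factor of two); 1500-row table, 30
  diploids per pool, 50 replicates; both posterior medians within a
  factor two of truth counts as recovery (observed rate: 0.94).
* **Bottleneck calibration** — 200 TPM-equilibrium fixtures (θ = 5, 25
  diploids, 10 loci) for the type-I rate of the heterozygosity-excess
  test, with (k, n)-conditional equilibrium distributions memoised
  across fixtures (800 retained replicates each); 200 SMM fixtures for
  the M-ratio equilibrium rate.

The acceptance script (`scripts/acceptance.R`) reruns all of the above
from scratch under a caller-supplied seed and writes the resulting
numbers as JSON.

## Known limitations

* The coalescent kernel supports piecewise-constant sizes and
  instantaneous events only — no continuous growth, no migration
  matrices within scenario timelines (symmetric migration exists only
  in the island generator).
* One μ and one P per dataset; no per-locus mutation-rate
  heterogeneity, no single-nucleotide indel component.
* Jost's D multi-locus harmonic mean is restricted to positive
  per-locus values.
* The exhaustive Q-matrix alignment is limited to K ≤ 8; no greedy
  fallback.
* GeoTIFF output is not provided; rasters are ESRI ASCII grids.
* The heterozygosity-excess permutations and equilibrium simulations
  are Monte-Carlo; p-values carry simulation noise of order
  1/√(replicates).
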