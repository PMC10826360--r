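---
title: "Methods: simulating uneven sequencing depth and benchmarking normalizations"
author: "rarebench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating uneven sequencing depth and benchmarking normalizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rarebench)
```

# What the benchmark measures

Microbiome count tables carry an unwanted technical covariate — library size
— that varies by an order of magnitude or more between samples. A
normalization strategy succeeds if downstream analyses respond to community
composition and not to depth. `rarebench` probes that with three readouts on
simulated two-group data sets: best-matched clustering accuracy on distance
matrices, PERMANOVA type-I error (effect size 1.00) and power (effect sizes
above 1.00), and Wilcoxon comparisons of per-sample richness and Shannon
diversity. Six normalizations are compared: raw counts, relative abundance,
a negative-binomial variance-stabilizing transform (VST), upper-quartile
log-fold-change scaling (UQ log-CPM), a single subsampling to a common
depth, and rarefaction (repeated subsampling with the *metric*, never the
counts, averaged across iterations).

# The synthetic data generator

## Parent communities

`makeSyntheticParents()` draws two lognormal species-abundance
distributions over a shared OTU index. Lognormal relative abundances are the
standard null model for rank-abundance structure in microbial communities;
the shape parameter (`sadShape`, the lognormal sigma) defaults to 2.0, which
gives the few-dominant/many-rare profile typical of 16S surveys. The two
parents share `overlapFraction` of the OTUs (default 0.45, mirroring the
published parent pair this generator emulates: roughly 900 of 2,000 OTUs
shared between two pooled real communities, with each parent's support near
1,300–1,600 OTUs); the remaining OTUs are split evenly into private
supports. A random bifurcating topology with exponential(1) branch lengths
stands in for a real phylogeny — it is labelled synthetic throughout and is
only used to give UniFrac a tree with realistic depth variation, not to
model real clade structure. `buildParentsFromCounts()` provides the
real-data path: OTUs observed in more than one pooled sample, ranked by
prevalence then total abundance, top-*n* pooled within group and
renormalized.

What the generator deliberately does **not** emulate: taxonomic correlation
between OTU abundances, overdispersion beyond multinomial resampling of a
fixed mixture, chimeras and sequencing error, and real tree topology.
Passing results therefore show how normalizations respond to *depth
structure*, which is the variable under study, not to every property of
real data.

## Sequencing-depth models

Two depth distributions are modelled, both anchored to a published
26-sample range of 58,688–2,357,181 reads:

* `empirical_resample` — 26 base depths drawn once per grid from a normal
  distribution clipped to that range (the published distribution was
  normal; only its moments are public, so the default sd of 574,623 reads
  spans the printed range at about ±2 sd around the printed mean of
  1,085,256.8). Eighty per-sample depths are resampled from the 26 with
  replacement, so each base depth is reused 80/26 ≈ 3.08 times on average.
* `log_scaled` — 80 depths spaced evenly on the log scale across the same
  range and used exactly once each. The rounded vector has median 372,040
  and mean 629,825 reads, and a 40.16-fold range.

Depths are then rescaled so their median equals the target
(1,000–50,000 reads), rounding to the nearest integer with a floor of one
read — the rounding direction is unspecified upstream, and nearest-integer
preserves the median and rank order. Group labels are either shuffled
independently of depth, or fully confounded: the 40 smallest depths in
group A, the 40 largest in group B.

## Count simulation and filtering

Each sample is one multinomial draw of its assigned depth from its group's
mixture `f·p_own + p_other` (renormalized). Multinomial sampling is the
natural reading of "sampling to depth" for proportion-valued parents —
without-replacement sampling has no finite template here. The mixing form
was chosen because effect size 1.00 is then *exactly* null and group
separation is monotone in the effect size.

The optional two-step rare-OTU filter treats each step's removal rule as a
conjunction (an OTU must fail both clauses of a step to be removed):
step 1 removes OTUs with total < 3 *and* prevalence < 3; step 2 removes
OTUs with more than one read in at most 5% of samples *and* total at most
half the per-group size (20 for 40-sample groups). The source description
is grammatically ambiguous between conjunction and two independent sweeps;
the double-negative phrasing reads most naturally as a conjunction, which
is what the package implements and tests. The filter is idempotent and
never touches surviving counts.

# Normalizations

**Threshold quantiles.** Subsampling and rarefaction operate at a
minimum-library-size threshold *N*<sub>*L*,*m*</sub> set to a percentile of
the observed depths (0, 5, 10, 15, 20, 25 or 40). For `n` samples at
percentile `q`, `pickThreshold()` uses the `floor(q/100·n)+1`-th smallest
depth, so with distinct depths exactly `floor(q/100·n)` samples are
discarded — 12 of 80 at the 15th percentile, which is what caps accuracy at
68/80 = 0.85 when all retained samples cluster correctly. (The plain
inverse-ECDF quantile would discard one sample fewer at integer `q·n/100`;
the chosen rule matches the documented sample-removal arithmetic.) Raw,
relative-abundance, VST and UQ tables always keep every sample.

**VST.** Size factors come from median-of-ratios against the geometric-mean
reference on pseudocounted counts (pseudocount 1 — microbiome tables are
zero-heavy, and the choice of pseudocount is consequential; it is exposed
as an argument). A common mean-dispersion curve α(μ) = a₀/μ + a₁ is fit by
method of moments: per-OTU dispersion estimates (v−μ)/μ² regressed on 1/μ.
The closed-form transform for that curve,
log₂[(1 + a₀ + 2a₁q + 2√(a₁q(1 + a₀ + a₁q)))/(4a₁)], is monotone within a
sample, approaches log₂ of the normalized count for large counts, and can
be negative for small ones. When the asymptotic dispersion estimate is
non-positive (common for near-multinomial simulated counts), a₁ falls back
to 10⁻⁸ with a warning; the transform then behaves like a square-root-type
Poisson stabilizer, which is the correct small-dispersion limit. The test
surface is this contract — monotonicity, asymptotic log₂, variance
flattening on negative-binomial counts — not bit-equality with any specific
RNA-seq package, whose exact internals are out of scope.

**UQ log-CPM.** Per-sample factors are the 75th percentile of the sample's
nonzero counts divided by its library size, rescaled to geometric mean 1;
the output is log₂(CPM + 1) against the effective library size
(depth × factor). Placing the pseudocount on the CPM scale makes the output
exactly invariant to doubling a sample's counts and maps every zero to the
same value in every sample — which is also why UQ output is excluded from
richness comparisons.

**Negative values.** The fraction of negative VST cells is recorded per
replicate (`detectNegativeFraction()`). Pairing VST with Bray-Curtis or
weighted UniFrac is disallowed by default — those definitions are
meaningless on signed data — and available only behind an explicit
`pathology = TRUE` flag for studying exactly that failure mode; by default
VST feeds Euclidean distances only, and inadmissible pairs are recorded as
`NA` outcomes rather than errors so no grid cell is silently dropped.

# Distances, clustering, tests

Bray-Curtis and Euclidean go through `vegan`/`stats`. UniFrac is computed
by postorder accumulation of per-sample branch masses (unweighted: unique
over shared branch length on presence/absence; weighted: Σℓ|A−B|, divided
by its maximum Σℓ(A+B) when normalized — the normalized variant is the
default, matching common usage, with a flag to disable). The Poisson
dissimilarity is the published log-likelihood-ratio form with total-count
size factors and a power transform whose exponent is chosen so the Poisson
goodness-of-fit statistic matches its degrees of freedom. Top-MSD is the
square root of the mean of the `nTop` (default 500, clamped to the OTU
count) largest squared per-OTU log differences; the exact shrinkage
behavior of its RNA-seq ancestor is deliberately out of scope.

Clustering: PAM (BUILD + swap k-medoids on the dissimilarities,
deterministic), k-means on the distance-matrix rows as feature vectors
(10 restarts, seeded; rows-as-features mirrors the source analysis but is
geometrically unorthodox, so a PCoA-embedding alternative sits behind
`kmeansEmbed = TRUE`), and complete-linkage hierarchical clustering cut at
k = 2 (the linkage is the ecosystem default; only "hclust and cutree" is
specified upstream). Accuracy is best-matched over the two
cluster-to-group assignments with removed samples counted as errors, so a
forced two-cluster split of a null data set tops out at 41/80 ≈ 0.51.

PERMANOVA is implemented from its definition (pseudo-F from squared
distances; p = (1 + #{F* ≥ F})/(n_perm + 1) over seeded label
permutations, 999 by default for a single-factor design) and is verified in
the tests against both exhaustive enumeration of balanced labelings and
`vegan::adonis2`'s F statistic. The Wilcoxon test uses the exact null for
groups of at most 10 tie-free values and the continuity-corrected normal
approximation otherwise.

# Orchestration and problem sizes

Every cell's seed is a polynomial hash of the master seed and the cell's
key (condition fields, replicate, stage), so adding conditions never
perturbs existing replicates, reruns are bit-identical, and interrupted
runs resume from checksummed per-replicate chunk files. Results are one
long-format TSV (condition key + normalization + threshold + distance +
measure + value), which makes the aggregations one `split`/`tapply` away.

The package's working scale (its "desk" preset and the defaults used by
the test suite and acceptance script) is 200-OTU parents, 25 rarefaction
iterations, 25–100 replicates per condition and 999 permutations — small
enough to iterate on a laptop while leaving every qualitative signature
intact. The published full design (2,000 OTUs, 100 iterations,
8 × 2 × 5 × 2 conditions × 100 replicates) is available as
`gridPreset("full")` and runs in hours on one CPU. One arithmetic note:
the source description of that design multiplies to 16,000 data sets while
announcing 1,600; the grid here follows the listed factors and reports
whatever count they imply.

# Known limitations

* Rarefaction's variance advantage is demonstrated on the metric scale
  (accuracy medians and IQRs); no claim is made about optimality of the
  iteration count beyond the conventional 100.
* The VST and UQ implementations honor contracts, not upstream package
  internals; absolute values will differ from DESeq/edgeR even where the
  qualitative behavior matches.
* Type-I inflation under confounded depths is reproduced at desk scale
  with 25–100 replicates; rates of exactly 1.0 observed there carry wide
  binomial intervals.
* TMM and RLE normalizations and the BCV distance are counted in the
  280-combination grid arithmetic but not computed, since their results
  were never presented in the analyses this framework emulates.
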