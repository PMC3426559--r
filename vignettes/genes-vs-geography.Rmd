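---
title: "Quantifying the similarity between genes and geography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the similarity between genes and geography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genogeo)
```

## The question and the statistic

Under isolation by distance — gene flow that is mostly local in space —
allele frequencies drift apart gradually with distance, and a principal
component analysis of genome-wide genotypes tends to arrange individuals
in a plane that resembles the map of their sampling locations. `genogeo`
quantifies that resemblance. Two point configurations are compared: the
**PC map** (each individual at its PC1–PC2 coordinates) and the
**geographic map** (each individual at its population's location).
Procrustes analysis finds the translation, scaling, rotation and
(optionally) reflection of the PC map minimizing the sum of squared
distances to the geographic map while preserving the PC map's internal
shape. With the minimized, dispersion-scaled sum of squares `D ∈ [0, 1]`,
the similarity statistic is `t0 = sqrt(1 − D)`: 1 for an exact
similarity-transform match, 0 for none. We fix geography and transform the
PC map, and also report the fitted rotation angle (degrees
counterclockwise; under reflection, the angle of the rotation factor after
writing the orthogonal part as an x-axis reflection followed by a
rotation).

The fit is closed-form: center both sets, take the SVD of the 2×2
cross-covariance; `t0` is the sum of singular values divided by the
geometric mean of the two dispersions. When reflections are excluded and
the unconstrained optimum reflects, the smaller singular value enters
negatively. Reflection is allowed by default — a PC map is only defined up
to the signs of its axes — and a flag exposes the rotation-only family.

## The pipeline and its parameters

**Standardization.** Genotypes are reference-allele counts `c ∈ {0,1,2}`.
With `p̂` the allele frequency among non-missing genotypes at a locus,
non-missing entries become `(c − 2p̂)/sqrt(2p̂(1−p̂))`; missing entries
and whole monomorphic columns (`p̂ ∈ {0,1}`, where the formula is
undefined) are set to zero. Every standardized column then has exactly
zero mean, so the `n × n` product matrix `YYᵀ` has the constant vector in
its null space and rank at most `n − 1`. `p̂` is the plain non-missing
mean divided by two, with no small-sample bias adjustment — the simplest
estimator consistent with the standardization.

**PCA.** We eigen-decompose `YYᵀ` and keep `n − 1` components. Scores are
`sqrt(λ_k)·u_k`, so each PC's variance on the plot equals `λ_k/n` and the
plot reflects how much variation each axis carries (unlike equal-variance
eigenvector plotting). Variance explained is `λ_k / Σλ_j`. Tiny negative
eigenvalues (within `1e−8·λ_1` of zero) are clipped to zero; anything more
negative is an error. Ties between eigenvalues make the component order
solver-dependent, so tests avoid constructing exact ties.

**Quality control.** Individuals with *strictly more than* 5% missing
genotypes are removed first (exactly 5% is retained — the threshold is a
strict inequality), the fraction being computed over the loci of the
matrix at hand. Then, iteratively: standardize, run PCA, flag anyone
whose score on one of the top `min(10, n−1)` PCs is more than 10 sample
standard deviations from that PC's mean, remove the flagged, repeat until
a pass flags nobody. The SD is recomputed from the current iteration's
scores; because each PC is standardized by its own spread the decision is
unaffected by the eigenvalue scaling of the scores. A practical note on
the 10-SD rule: a lone outlier's z-score on the component it dominates
cannot exceed about `sqrt(n)`, so in cohorts of a hundred individuals or
fewer a 10-SD excursion is unreachable and the rule is effectively
inactive — our outlier tests therefore use cohorts of several hundred.

**Geography.** Coordinates are decimal degrees, negative in the southern
and western hemispheres. For worldwide analyses, longitudes west of a
threshold (default −40°, roughly the Atlantic mid-line; the value is
configurable) are shifted +360° so the Americas sit east of Eurasia, and
the Gall–Peters equal-area projection (standard parallel 45°, unit
radius) maps to the plane. Regional analyses use raw longitude/latitude
as an isotropic plane — adequate away from high latitudes, distorted near
them. None of these unit choices matter for `t0`, which is invariant to
any similarity transform of either configuration (verified numerically in
the tests); they matter only for how the superimposed map is drawn.

**Permutation test.** The null hypothesis is that no geographic pattern
exists in the population structure. Each permutation reassigns the
population locations uniformly at random among the populations (locations
are permuted, individuals of a population move together) and recomputes
`t0` against the fixed PC map — the PCA is not recomputed, as genotypes
are untouched. With `M` permutations at least as similar as observed out
of `N`, the estimate is `p̂ = M/N`, displayed `< 1/N` when `M = 0`; the
`M/N` convention (rather than `(M+1)/(N+1)`) is what makes a zero count
reportable as `p < 10⁻⁵` at `N = 100,000`. Ties count toward `M`, which
is conservative. For 8 or fewer populations an exhaustive mode enumerates
all `K!` assignments, where `p̂` is exact. Random permutations are drawn
independently (collisions allowed), which is immaterial when `N ≪ K!`;
with few populations and many permutations the identity assignment is
redrawn occasionally, which only inflates `p̂` slightly — the calibration
test bounds the resulting type-I error within [0.03, 0.07] at nominal
0.05.

**Leave-one-out.** Each population is excluded in turn; PCA is rerun from
the post-QC individual set (the outlier search is not repeated), and the
new PC1–PC2 map is scored against geography (`t0′`) and against the
original map on the common individuals (`t_PCA`). A population whose map
position contradicts its genetic affinities raises `t0′` when removed;
a negligible population leaves `t_PCA ≈ 1`.

**Marker curves.** Loci are subsampled uniformly without replacement with
a seed-determined draw that depends only on `(seed, L_sub)` and the shared
locus list, so different datasets over the same loci are scored on
identical marker sets and their curves are comparable.

**FST.** The Weir–Cockerham moment estimator in genotypic form: per
locus, per-population sample sizes, allele frequencies and *observed*
heterozygote frequencies (no Hardy–Weinberg assumption) yield the
among-population, between-individual and within-individual variance
components `a, b, c`; the multi-locus estimate is `Σa / Σ(a+b+c)` — a
ratio of sums, not a mean of per-locus ratios. Loci with fewer than two
populations carrying data, average sample size of one, or monomorphic
overall contribute to neither sum. Negative estimates (expected when true
differentiation is ~0) are reported as computed.

## What the simulator emulates — and what it does not

`simulate_lattice_dataset()` generates the isolation-by-distance regime
the pipeline targets: per locus an ancestral frequency is drawn uniformly
(default 0.1–0.9), per-population deviations come from a zero-mean
Gaussian process over the population locations with covariance
`σ²·exp(−d/ρ)` on the logit scale, and genotypes are binomial draws from
the population frequencies (clipped to [0.001, 0.999]; loci can still go
monomorphic by sampling, which standardization handles). The logit-normal
spatial model was chosen over stepping-stone or coalescent simulation
because it gives explicit, fast control of the spatial covariance — the
only property the pipeline's statistics consume. It does **not** produce
linkage disequilibrium, site-frequency-spectrum realism, admixture
events, or mutation-model detail, so passing tests demonstrate recovery
of spatial frequency structure, not robustness to those features of real
data. `simulate_balding_nichols()` complements it with an exchangeable
model whose true FST is the parameter `F` (population frequencies are
Beta-distributed around the ancestral value with variance `F·p(1−p)`),
giving a known truth for estimator calibration; under a two-population
version the PC1 variance share approaches `F`, which the tests assert
within 30% relative.

Study conditions used by the tests and the acceptance script, chosen once
as representative regimes: a **strong** regime (5×5 lattice, 10
individuals per population, 2,000 loci, σ = 1, ρ = 30°; FST ≈ 10%,
`t0 ≈ 0.98`) where the PC map essentially is the map, and a **weak**
regime (4×4 lattice, 15 per population, 20,000 loci, σ = 0.15, ρ = 30°;
FST ≈ 0.002) where the similarity is still climbing at 20,000 markers —
the two ends of the differentiation spectrum that real regional datasets
span. Null-calibration runs use 8 populations at *irregular* random
locations: symmetric lattices create exact `t0` ties among permuted
assignments (a rotation of a square is still the square), which distorts
permutation ranks; irregular layouts avoid the degeneracy.

## Numerical choices and degenerate inputs

- Procrustes requires ≥ 3 points and non-zero dispersion in both
  configurations; all individuals at one location is an error, not a fit.
- The optimal scale is constrained positive; a 180° rotation ties at
  +180° (the reported angle lies in (−180°, 180°]).
- `t0` is clipped into [0, 1] against floating-point overshoot; the
  residual identity `Σ‖residual‖² = D·(target dispersion)` holds to 1e−9
  relative and is asserted in the tests.
- Eigen- and SVD-paths of the PCA agree to 1e−8 (relative) on matrices up
  to 50×500; component signs are arbitrary and absorbed by Procrustes.
- The genotype container rejects values outside {0, 1, 2, NA}, duplicate
  individual or locus IDs, and individuals missing from the population
  map; the VCF reader maps diploid `GT` to alternate-allele counts,
  treats `./.` as missing, and refuses non-biallelic or non-diploid
  records by locus name.

## Problem sizes

The test suite and acceptance script run entirely on simulated data at
sizes a laptop handles in seconds per stage: cohorts of 36–420
individuals for unit and QC tests, 250 individuals × 2,000 loci for the
strong-regime pipeline, 240 × 20,000 for the weak-regime marker curves,
500 replicate datasets of 24 individuals for permutation calibration, and
300 × 5,000 for FST recovery. These sizes were chosen so every asserted
property (oracle agreement, planted-outlier recovery, type-I calibration,
truth recovery within stated bands) has comfortable statistical margin at
desk scale; the pipeline itself has no size-specific logic and is
routinely run at tens of thousands of markers.

## Known limitations

- Only the first two PCs enter the Procrustes comparison; the pipeline
  takes no position on higher-dimensional structure.
- Unprojected regional coordinates treat 1° of longitude as 1° of
  latitude, which overweights east–west distances at high latitude.
- The permutation test conditions on the observed PC map; it tests the
  arrangement of locations, not uncertainty in the PCA itself.
- FST is a single pooled estimate; pairwise matrices and confidence
  intervals are out of scope.
- No LD pruning or relatedness filtering: the estimators assume
  approximately independent loci and unrelated individuals.
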