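---
title: "Methods: dynamic connectivity, brain states and entropy in consdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic connectivity, brain states and entropy in consdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consdyn)
```

consdyn implements a complete analysis chain for characterising how loss of
consciousness reshapes brain integration and functional diversity in
resting-state fMRI: voxelwise complexity and connectivity maps, time-resolved
functional connectivity, decomposition of time windows into integrated and
segregated brain states, graph-theoretical summaries of each state, node-wise
connectivity entropy, and permutation-based group statistics. This vignette
explains each model and the numerical decisions behind it, what the
synthetic-data generator emulates, and what the package's tests do — and do
not — establish about real data.

## Voxelwise measures

**Sample entropy.** `sampleEntropy()` quantifies the unpredictability of a
timeseries as SampEn = −log(A/B), where B counts unordered pairs of distinct
length-m templates whose Chebyshev distance is at most r, and A the same for
length-(m+1) templates. Defaults are m = 3 and r = 0.6 × SD of the series,
the standard choice for resting-state fMRI. Three conventions matter and are
deliberate:

* Both template lengths use the same T − m templates, so a constant series
  gives A = B and SampEn exactly 0 rather than a spurious positive value.
* The similarity criterion is a closed inequality (distance ≤ r). With a
  strict inequality a constant series would have no matches at r = 0 and
  SampEn would be undefined instead of 0.
* r is scaled by the population (divide-by-T) SD, making SampEn invariant to
  affine rescaling of the signal.

When no template pair matches at either length the result is flagged
undefined (`defined = FALSE`) rather than silently 0; `sampenMap()` excludes
such voxels from the output mask.

**Intrinsic connectivity contrast.** `iccMap()` assigns each in-mask voxel
the sum of squared Pearson correlations with every other in-mask voxel — a
degree-like index of global connectivity. The raw sum is not divided by the
number of voxels; standardisation is done by `normalizeZscoreMap()`, which
centres and scales by the in-mask population SD so the map has mean 0 and
unit variance. A constant map normalises to all zeros by convention.
`smoothMapGaussian()` provides the 10 mm FWHM smoothing used for entropy
maps; it is mask-aware (the smoothed map is divided by the smoothed mask) so
values near the mask boundary are not dimmed. `binarizeAndOverlap()`
intersects binarised significance maps, e.g. entropy ∩ ICC within a dataset
and then across datasets.

## Static and dynamic functional connectivity

`staticFC()` is the Pearson correlation between regional timecourses over
the whole scan. `dynamicFC()` slides a tapered window along the scan with a
1-TR step: the taper is a 22-TR rectangle convolved with a 3-TR-SD Gaussian,
cropped to the central 23 taps and renormalised (`buildTaper()`). The taper
weights act as observation weights in a weighted Pearson correlation
(weighted means and covariances via `stats::cov.wt`), not as a multiplier on
the signal, which preserves the correlation scale. A T-timepoint series
yields T − 22 windows: 229 windows for T = 251 and 273 for T = 295 — these
window counts are the binding contract of the construction. Because the
rectangle length is even, the Gaussian kernel is sampled on a half-integer
grid so the composite taper is exactly symmetric; the degenerate σ = 0 case
returns the bare rectangle.

## Modularity and cartographic profiling

Each windowed matrix is kept weighted and signed. `louvainSigned()`
maximises the asymmetric two-term signed modularity: positive weights are
scored against a strength-product chance term at full weight 1/v⁺, negative
weights subtract at the weaker scaling 1/(v⁺+v⁻), so modules are groups of
mutually positively correlated regions whose anticorrelations point
outward. Conventions: the chance term e±ᵢⱼ = s±ᵢ s±ⱼ / v± is summed over all
node pairs including i = j (this makes the single-module partition of a
uniform all-positive graph score exactly Q = 0); the resolution parameter is
γ = 1; the algorithm restarts 100 times with randomised node sweep order and
the maximum-Q partition is kept, ties resolved by first occurrence; Q is
recomputed directly from the returned assignment as a consistency guarantee.

`nodeCartography()` derives, from positive weights only, the participation
coefficient Pᵢ = 1 − Σₛ (κᵢₛ/kᵢ)² (0 for a provincial node, bounded by
1 − 1/M) and the within-module z-score zᵢ, standardised over the node's own
module with the sample SD. Nodes with zero positive strength get P = 0;
modules with zero strength SD (including singletons) give z = 0.

## Integrated and segregated states

`cartographicProfiles()` converts each window into a joint histogram of the
node (P, z) pairs — 10 × 10 bins, P over [0, 1], z over [−5, 5] with values
clipped into the outer bins — row-normalised to proportions. The bin
geometry is a package decision (the clustering literature it follows does
not fix one); a fixed geometry gives every window the same feature length
and makes histograms comparable across subjects. `kmeansStates()` clusters
the window histograms with k = 2 k-means under the correlation distance
1 − Pearson r, 500 random restarts, mean centroid updates, and empty
clusters reseeded at the point farthest from its assigned centroid; the
restart with the lowest total within-cluster distance wins. The cluster
whose member windows have the higher mean participation coefficient is the
integrated state. Per state, `stateCentroids()` takes the elementwise median
of member windows, and `timeInState()` reports occupancy fractions.
Clustering is performed per subject and condition. A degenerate outcome
(constant feature rows, or an empty cluster in the best restart) raises an
error rather than returning an arbitrary split.

## Brain graphs and their metrics

`proportionalThreshold()` retains the top density × N(N−1)/2 edges ranked by
signed weight — anticorrelations are weak candidates, not strong edges — with
ties broken by (row, column) order; retained edges optionally binarise to 1.
The default density grid is 10–25% in 5% steps with metrics averaged across
densities; 30–50% and binarised variants serve as robustness checks.
`weightedPathLength()` uses reciprocal-weight edge lengths and Dijkstra
shortest paths, averaging over ordered pairs; unreachable pairs are excluded
from the mean and counted, a finite-mean convention that keeps sparse graphs
usable. `weightedClustering()` implements the geometric-mean triangle
intensity with weights scaled by the graph maximum, Cᵢ = 2tᵢ/(kᵢ(kᵢ−1)) with
binary degree and Cᵢ = 0 below degree 2. `rewireNull()` randomises topology
by degree-preserving double-edge swaps (100 attempted swaps per edge);
weights travel with the rewired edges so both the degree sequence and the
weight multiset are preserved exactly. `smallWorldness()` normalises mean
clustering and path length by the means of 100 rewired nulls and averages
S = (C/C_rand)/(L/L_rand) across the density grid; random-like graphs score
S ≈ 1 and lattice-like graphs well above 1.

## Connectivity entropy

`connectivityEntropyNodes()` histograms each node's N − 1 off-diagonal
connectivity values into 10 equal-width bins and normalises the Shannon
entropy by log 10, bounding every value in [0, 1]. The bin edges are fixed
over [−1, 1] — correlations live there, and fixed edges make entropies
comparable across subjects and states; the source methodology does not
record its edge convention, so this is a package decision. The diagonal
self-correlation is excluded as uninformative. Network summaries
(`summarizeByNetwork()`) average node entropies within seven canonical
resting-state networks.

## Group statistics

`permutationTTest()` is two-sided: paired samples sign-flip the within-pair
differences; unpaired samples shuffle group labels around the classic
pooled-variance t. Whenever the permutation space is small enough (2ⁿ sign
patterns or C(n₁+n₂, n₁) assignments within the permutation budget) the null
is enumerated exhaustively and the p-value is exact; sampled p-values use
the add-one convention (1+b)/(n+1), which keeps them valid and nonzero.
Hedges' g applies the small-sample correction 1 − 3/(4df − 1); the paired
variant standardises by the SD of differences. `bhFdr()` wraps the standard
Benjamini–Hochberg step-up. `edgewiseContrast()` tests every unique edge
with permutations shared across edges, applies BH-FDR over the N(N−1)/2
edges, and zeroes non-survivors; `combineCommonDifferences()` then applies
the sign-consistency rule (both positive → minimum; both negative →
maximum, i.e. the smaller magnitude; otherwise 0), so a surviving edge marks
a change reproduced in direction across datasets with its weight a lower
bound on the common alteration. Voxel-map group comparisons reuse the same
permutation + FDR machinery; this is a deliberate method variant — the
common alternative is a parametric GLM with cluster-extent familywise
correction, which needs spatial smoothness estimation that is out of scope
here.

## The synthetic cohorts: what they emulate and what they do not

`simulateCohorts()` builds the two study designs the statistics expect: a
paired 16-subject cohort scanned awake and under anaesthesia-like
unconsciousness (T = 251, TR = 2 s), and 22 unpaired patient-like runs
(T = 295) compared against the 16 awake controls. Each run draws, per TR, a
90-region vector from a block-structured Gaussian — 5 modules of 18 regions,
within-module correlation 0.5 — whose between-module correlation switches
between an integrated regime (0.35) and a segregated regime (0.05) following
a symmetric two-state Markov chain with switching probability 0.02 per TR.
Temporal structure comes from AR(1) mixing (coefficient 0.2 in conscious
runs). Unconscious runs plant the group effects the analysis should find:
between-module coupling in the integrated regime drops by 0.15, and the
AR(1) coefficient rises to 0.5, which lowers sample entropy. These values
are the generator's fixed study conditions: the modular block structure with
a clear within/between contrast is what gives cartographic profiling
something to detect, 0.02 per TR yields a handful of regime switches per
scan (dwell times long relative to the 23-TR window), and AR coefficients of
0.2 vs 0.5 span the range typically reported for denoised BOLD.

The generator is intentionally minimal. It does not emulate hemodynamic
convolution, physiological noise spectra, spatial autocorrelation, scanner
drift, motion artefacts, or lesioned anatomy. Passing tests therefore show
that the implementation recovers the statistical structure it targets under
a faithful, known generative model — not that the pipeline is robust to
everything real fMRI contains.

## Known limitations and numerical notes

* **Window-level cartography is noise-limited.** With 23-tap windows, the
  per-window Louvain partition and the (P, z) histograms fluctuate
  substantially; on synthetic subjects the regime information retained by
  the histogram features is distinctly less than what the raw between-module
  weights carry. State-recovery agreement therefore varies across subjects
  (roughly 0.55–0.90 on regime-balanced default subjects), and windows that
  straddle a regime switch are intrinsic label noise. The state-recovery
  check uses the first default-cohort run whose planted sequence actually
  visits both regimes — recovery is undefined for a run that never switches,
  since a forced two-way split of single-regime data has no ground truth to
  agree with.
* **Butterworth filtering is not exactly idempotent.** Denoising applies a
  zero-phase 4th-order Butterworth band-pass (0.008–0.09 Hz by default)
  forward and backward. The detrending/confound regression is an orthogonal
  projection and exactly idempotent; a second band-pass application
  re-attenuates energy near the band edges by a few percent. An ideal
  brick-wall filter would be exactly idempotent but rings badly on finite
  series, so the Butterworth is the right trade-off for fMRI.
* **Despiking scale.** The tanh squashing x ↦ c·tanh(x/c) uses
  c = 4 × MAD of the demeaned series: scale-free, and effectively linear for
  excursions below about 2 MAD.
* **Thresholded graphs are nonnegative.** Ranking by signed weight drops
  anticorrelations first; in the rare case a nonpositive edge would be
  retained (very high densities on strongly anticorrelated matrices) it is
  dropped with a warning, since reciprocal-weight path lengths are undefined
  for nonpositive weights.
* **Determinism.** Every stochastic routine takes a seed; the pipeline
  derives all stage seeds from one master seed, and identical configurations
  reproduce identical numbers.
* **Problem sizes in the test-suite.** Unit tests run reduced cohorts
  (e.g. 3 + 4 subjects, 12–20 regions, 60–120 timepoints) and moderate
  restart counts; the planted-effect and state-recovery checks use the
  full default cohort sizes with 50–100 Louvain restarts per window and
  300–500 k-means restarts, which the authors consider sufficient for
  stable optima at these matrix sizes. Null-calibration replicates for the
  common-difference matrices run on the static-FC path, where the global
  null behaviour of the BH procedure is identical to the state-specific
  path at a fraction of the cost.

## A worked miniature

```{r example, eval = FALSE}
spec <- cohortSpec(nSubjectsA = 4, nSubjectsB = 4, nRegions = 20,
                   nModules = 4, nTimepoints = c(A = 120, B = 120), seed = 2)
cfg <- pipelineConfig(spec = spec, louvainRepeats = 20, kmeansRestarts = 100,
                      nNulls = 20, nPerm = 1000, seed = 2)
report <- runPipeline(cfg)
report$groupStats$fractionIntegrated$awakeVsDeep
report$commonDifferences$integrated
```

The report bundles every per-run object (static FC, state assignment,
graph and entropy summaries), the three group comparisons (paired awake vs
deep, unpaired control vs patient, and a no-effect patient subgroup split),
and the common-difference matrices for the static, integrated and
segregated connectivity.
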