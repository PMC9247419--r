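---
title: "Methods: comparative scaling of white-matter connectomes"
author: "connallom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative scaling of white-matter connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connallom)
```

This vignette is the package's own account of its methods: the statistical
model and its assumptions, the network statistics, the design decisions made
where the underlying procedures admit more than one reasonable
implementation, and what the synthetic-data generator does and does not
emulate.

## The comparative regression model

Species are not independent observations: close relatives resemble each
other because they share most of their evolutionary history. Under a
Brownian-motion (BM) model of trait evolution, a trait performs a random
walk along the branches of the phylogeny, and the expected covariance
between the trait values of two species equals the branch length they share
on the path from the root. `brownian_covariance()` builds this matrix
directly from a time-calibrated tree; polytomies need no special handling
because the covariance is defined purely by shared path lengths.

`pgls()` fits a linear regression whose residual covariance is this BM
matrix with the off-diagonal entries multiplied by Pagel's λ ∈ [0, 1]
(`lambda_transform()`): λ = 0 recovers ordinary least squares (independent
residuals), λ = 1 keeps the full phylogenetic covariance. λ is estimated by
maximizing the profile log-likelihood over [0, 1] with a bounded scalar
search (tolerance 1e-6), with both endpoints checked explicitly because the
profile is frequently monotone and the optimum sits on a boundary. We use
maximum likelihood rather than REML because it is the common default of
comparative-methods software and makes fits reproducible across
implementations.

Interpretation of the slope depends on the transform applied by the caller:

* **log10 on both sides** makes the slope an allometric scaling exponent
  (`trait_scaling_summary()` does this for trait pairs). The exponent is
  invariant to the log base; intercepts are reported base-10.
* **z-scores on both sides** (`ztrans()`) make the slope a standardized
  coefficient β, used for all network-metric regressions.

Confidence intervals and p-values for the slope use a t-distribution with
n − p degrees of freedom on the GLS standard errors, the standard PGLS
reporting convention. The coefficient of determination is computed in the
whitened (decorrelated) space: R² = 1 − RSS/TSS where both sums of squares
are taken after multiplying by the inverse Cholesky factor of the fitted
covariance and the total sum of squares is centered on the GLS estimate of
the mean; the adjusted version applies the usual (n − 1)/(n − p) correction.
These are deliberate, documented choices — "adjusted R²" admits several GLS
generalizations and we make ours explicit rather than assert it matches any
other package's.

Degenerate inputs are flagged rather than hidden: when the residual sum of
squares is numerically zero (perfectly collinear data), the fit is returned
with `degenerate = TRUE`, standard errors of 0, and undefined (NA) p-values.

`rma_fit()` provides the reduced major axis slope sign(r)·SD(y)/SD(x) as a
symmetric-fit robustness check; it errors on zero variance or zero
correlation, where the slope magnitude or sign is undefined.

This module operates on one value per species; averaging multiple
individuals per species into that value is the caller's responsibility.

## Parcellation

Comparative connectomics has no atlas that maps homologous regions across
all species, so regions are random but evenly dispersed:
`random_parcellation()` places region centers by farthest-point sampling on
the mesh's geodesic distance (shortest paths on the edge graph weighted by
edge length), starting from a seeded uniform vertex draw, then assigns every
vertex to its nearest center. Design choices, each of which the procedure's
verbal description leaves open:

* *Dispersal* is farthest-point sampling — deterministic given the first
  center, and provably well-spread (every new center maximizes its distance
  to the existing set).
* *"Closest"* uses geodesic distance, which respects the cortical sheet; a
  Euclidean switch exists (`distance = "euclidean"`).
* *Ties* in nearest-center assignment break toward the lowest center index,
  making labels bitwise reproducible given `(mesh, n_regions, seed)`.

The default resolution is 50 regions per hemisphere; 25 and 100 are
supported. On a uniform icosphere the resulting parcel sizes are equal
within a factor ≲ 3 (checked in the tests). The parcellation is built on
the left hemisphere and projected to the right through the meshes' vertex
correspondence (`project_contralateral()`), so region r on the right is the
designated spatial homolog of region r on the left.

## Connectomes, density, and connection length

`streamlines_to_connectome()` maps a streamline endpoint table to a
region × region matrix: weight = number of streamlines (NOS) joining two
regions, length = mean streamline arclength (the average physical distance
traveled by the reconstructed fibers). Streamlines with an unassigned
endpoint or with both endpoints in one region are dropped and tallied in a
discard log that always sums, with the counted streamlines, to the input
count. Synthetic connectomes have no streamlines, so their connection
lengths are Euclidean centroid distances.

Density is observed over possible region pairs, computed per hemisphere for
the comparative analyses (interhemispheric connections are excluded
throughout the network analyses). Because density itself varies with brain
size, `equalize_density()` thresholds every species down to a common
intrahemispheric density — by default the minimum across the set — before
path length, clustering, or asymmetry are computed. The mechanism (the
stated goal being equal density, not a particular algorithm) keeps each
hemisphere's strongest-NOS connections down to the target edge count, with
ties at the cutoff broken by weight and then lexicographic pair order. Edge
sets after equalization are always nested within the originals.

Connection-length distributions are made comparable across brain sizes by
binning each species' connection lengths into 10 equal bins spanning 0 mm to
the brain's anterior–posterior (AP) extent, so each bin covers 10% of AP
length; connections longer than the AP extent (possible for curved fibers)
fall into the longest bin. Binning counts unique connections, not
streamlines. The AP extent is the coordinate range along the designated AP
axis (y in the package's mesh convention). The short/long contrast sums
bins 1–2 against bins 3–10, where the size effect on long-range
connectivity is strongest.

## Graph metrics and the rewiring null

Characteristic path length is the mean shortest-path step count over
unordered node pairs; clustering coefficient is the mean over nodes of the
fraction of neighbor pairs that are connected (0 for degree < 2). Both are
binary metrics computed on the intrahemispheric subnetwork of each
hemisphere separately. Because degree-preserving rewiring can disconnect a
network, path length averages over reachable pairs only and reports the
unreachable fraction alongside.

Raw values of both metrics depend strongly on size and density, so each is
normalized by the mean of its distribution over Maslov–Sneppen rewired
reference networks: repeated double-edge swaps, rejecting any swap that
would create a self-loop or multi-edge, with a budget of 10 attempts per
edge (attempts, not successes — the standard convention) and exact
preservation of every node's degree. Normalization is the ratio
raw/null-mean, the conventional small-world-style normalization; the null
mean and SD are recorded so a z-score can be formed by the caller if
preferred. The reference ensemble defaults to 1000 networks per connectome.

Supplementary hub statistics (`hub_metrics()`) are degree, unnormalized
shortest-path betweenness with equal splitting across tied paths, and the
rich-club curve φ(k) = density of the subgraph on nodes of degree > k.

## Connectivity asymmetry

The asymmetry statistic compares each left-hemisphere region A with its
right-hemisphere spatial homolog A′ through their connectivity profiles —
their weight vectors over the other regions of their own hemisphere,
indexed by homologous targets. To remove cross-species (and
cross-hemisphere) differences in overall connection strength, weights are
first resampled within each hemisphere by a rank-preserving quantile map
onto a normal reference with M = 1, SD = 0.2: the k-th smallest of m
weights receives the normal quantile at (k − 0.5)/m. After this step the
two hemispheres carry identical weight distributions, so only rank and
placement differences can register; the statistic is consequently invariant
to any monotone rescaling of the raw weights. Resampling is per hemisphere
(not pooled per species) so that both hemispheres' moments match exactly;
ties are broken by edge order.

The pair score is the mean absolute weight difference over connections
present in both profiles (identical profiles score exactly 0); pairs sharing
no connection are excluded from the species mean rather than scored 0,
because a score of 0 would assert perfect symmetry exactly where no shared
evidence exists. A binary variant (1 − Jaccard overlap of presence/absence
profiles) is available as `mode = "binary"`.

The permutation test shuffles connection weights among the existing edges
within each hemisphere of each species — topology fixed, placement
randomized — recomputes every species' asymmetry, and refits the
standardized PGLS slope of asymmetry on the size trait; PGLS (not OLS) is
used for the refits for consistency with the observed fit. The empirical
p-value is (1 + #{null ≥ observed})/(1 + n_perm). Shuffling resampled
weights is equivalent to resampling shuffled weights, so the weights are
resampled once and permutations reshuffle them directly.

## The synthetic-data generator

`generate_study()` produces a complete comparative study with known ground
truth. Its defaults are the package's reference study conditions:

| Parameter | Default | Meaning |
|---|---|---|
| `n_species` | 14 | species count of the emulated sample |
| `volume_range_cm3` | 2.6–905 | cerebral-volume span (log-uniform via BM rescaling) |
| `exp_surface_volume` | 0.85 | generating surface-area exponent |
| `exp_wm_gm` | 1.10 | generating white-on-gray-matter exponent |
| `exp_cc_surface` | 0.88 | generating corpus-callosum exponent |
| `noise_sd_frac` | 0.05 | BM deviation SD as a fraction of predictor SD |
| `n_regions` | 50 | parcels per hemisphere |
| `decay_frac_range` | 0.30 → 0.12 | distance-decay length d0 / AP extent, smallest → largest brain |
| `density_range` | 0.52 → 0.34 | intrahemispheric density, smallest → largest brain |
| `asymmetry_range` | 0.05 → 0.40 | weight-perturbation level, smallest → largest brain |

Trees are pure-birth and ultrametric. log10 cerebral volume evolves by BM on
the tree and is rescaled onto the requested range; downstream traits follow
their scaling laws with BM deviations of the stated relative SD (an `iid`
residual option provides the no-phylogenetic-signal endpoint used in λ
calibration). Intercepts are anchored at brain-like magnitudes (gray matter
55% of cerebrum; at the smallest species, surface ≈ 11 cm², white matter
≈ 37% of cerebrum, 1 cm² of callosum per 90 cm² of surface) so generated
tables read like plausible data; intercept anchors never affect slopes.

Hemisphere surfaces are subdivided icospheres projected onto an ellipsoid
whose AP axis is 1.6× the others, scaled to each species' surface area; the
right mesh is the exact mirror of the left with an identity vertex
correspondence standing in for the left–right surface registration that real
cortices require. The default subdivision level for full studies is 3 (642
vertices per hemisphere): parcel counts of 25–50 remain well resolved while
keeping full multi-species studies fast; level 4 (2562 vertices) is used
where finer sampling matters.

Connectomes use an exponential distance rule: edge probability proportional
to exp(−d/d0) in centroid distance. The implementation draws one uniform
variate per pair, scores it by u·exp(d/d0), and keeps the k pairs with the
smallest scores, where k is the target edge count — exactly the
independent-draw model conditioned on its realized edge count, with the
proportionality constant equal to the k-th order statistic. This guarantees
the target density within one edge at every size instead of only in
expectation. At very strong decay (d0 ≲ 0.2·AP at 50 regions) the kept set
saturates to the k nearest pairs, so short-bin mass is monotone
non-increasing in d0 with a plateau in the saturated regime. NOS weights are
a discretized lognormal (meanlog 3, sdlog 1); the right hemisphere mirrors
the left, its weights multiplied by exp(a·ε) with ε ~ N(0, 1) at asymmetry
level a, so a = 0 yields an exactly mirrored connectome and an asymmetry
score of exactly 0. The exponential distance rule and the multiplicative
perturbation are generator conventions — minimal mechanisms producing the
intended qualitative regimes — not claims about biology.

With the bottleneck rule ON (d0/AP shrinking and asymmetry growing with
size), the pipeline recovers negative β for density and positive β for
normalized path length, clustering, and asymmetry across master seeds; with
all size dependence switched off, no association is detected. Both behaviors
are exercised in the test suite (10 master seeds each).

What the generator does **not** emulate: cortical folding, subject-level
variation within species, tractography artifacts (false positives/negatives,
length biases), distance-dependent reconstruction failure, or any
functional meaning of region placement. Passing tests therefore demonstrate
that the pipeline's statistics recover known generating structure under
clean geometric conditions — not that they are robust to the failure modes
of diffusion imaging.

## Problem sizes and determinism

Full-scale defaults follow the reference study conditions: 1000 rewired
reference networks per connectome and 1000 permutations. The package's own
test suite and acceptance script run scaled-down versions chosen to keep
the whole suite in the minutes range while leaving every statistical
conclusion intact: 25-region parcellations with 50-null ensembles for the
10-seed sign-recovery and null-calibration studies, 100 nulls for
single-network normalization checks, 100 replicates × 100 taxa for λ
recovery, and 200 replicates × 14 taxa for exponent recovery.

Every stochastic function takes an explicit seed, restores the caller's RNG
state, and derives per-stage streams from the master seed, so a pipeline
run is fully determined by (config, seed) — rerunning writes byte-identical
tables, and the manifest records the master seed together with an MD5 hash
of the analysis-relevant configuration (output paths and verbosity
excluded).

## Known limitations

* λ is profiled on a scalar grid boundary [0, 1]; no standard error or CI
  for λ̂ itself is reported.
* Path-length averaging over reachable pairs only (with the unreachable
  fraction reported) is one of several defensible conventions for
  disconnected graphs; comparisons with software that uses harmonic means
  or infinite penalties will differ on disconnected networks.
* The density-equalization mechanism (strongest-NOS retention) is a
  documented choice; alternative thresholding rules (e.g. by consistency
  across subjects) are out of scope because subject-level data never enter
  the package.
* Weighted path length and clustering, alternative evolutionary covariance
  models (Ornstein–Uhlenbeck, early burst), and ancestral-state
  reconstruction are not implemented.
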