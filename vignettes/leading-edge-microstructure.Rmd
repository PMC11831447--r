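---
title: "Spatial microstructure of the tumor leading edge: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial microstructure of the tumor leading edge: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`hexniche` analyses the spatial microstructure of a tumor leading edge —
the band around the tumor/normal borderline — from Visium-style spot-level
transcriptomics. Four analyses are provided, all operating on a pseudo-hex
spot lattice:

1. **Region partitioning**: tumor side, non-tumor side and stromal
   compartment from marker signatures (a KRT19-like tumor marker, an
   ALB-like hepatocyte marker, and a fibroblast + endothelial stromal
   signature).
2. **Quartile-tier co-localization**: per-spot products of quartile tiers
   (0–3) of two or three signals.
3. **Onion layering of tumor niches**: concave-hull (or hex-erosion)
   peeling of compact tumor aggregates into rim-to-core layers with a
   per-layer signature profile and a permutation trend test.
4. **Hex-neighbourhood correlation**: association between focal spots with
   an elevated signal (e.g. an SPP1+ macrophage signature) and a response
   signal (e.g. proliferation) averaged over their hexagonal
   neighbourhoods.

A negative-binomial synthetic generator with planted ground truth makes
every stage testable end-to-end without any external download.

# Signature scores, tiers and co-localization

Counts are normalized by scaling each spot to the median library size and
taking `log(1 + x)`. This is a deliberate, simple normalization choice:
every downstream decision in this package consumes ranks or quartiles of
signature scores, which are insensitive to the precise normalization
family, and a transparent rule keeps runs reproducible.

The score of a gene set at a spot is the mean of the scaled and centered
(z-scored across spots) expression of its genes. z-scores are capped at
±10 so a single extreme spot cannot dominate a module mean; a
zero-variance gene contributes 0. An optional `control_bins` mode
subtracts the mean z-score of expression-matched control genes (24 bins by
mean expression, 50 seeded controls per signature gene); the plain mean is
the default because the quartile tiering downstream removes most of the
background-level differences the control correction targets.

Tiers are quartiles of the score over a *scope* (default: the whole
slide): tier 0 for values at or below Q1, 1 up to Q2, 2 up to Q3, 3 above.
Quartiles use linear interpolation between order statistics (the common
default estimator) and boundary values fall to the lower tier, which makes
a constant signal all tier 0 — conservative, with no spurious "high"
spots. Co-localization of two or three tiered signals at a spot is the
product of their tiers: 0 whenever any signal is absent, maximal (9 or 27)
only when all are in their top quartile.

The scope of tiering is exposed because slides can legitimately be tiered
per region instead of whole-slide; whole-slide is the default.

The same multiplicative logic scores immunohistochemistry: staining
density (0–25/26–50/51–75/76–100% → 1–4) times staining intensity
(negative/weak/moderate/strong → 1–4), giving the 1–16 semi-quantitative
score implemented in `ihc_score()`.

# Regions

`assign_regions()` labels a spot `stroma` when its stromal score is in the
top quartile tier; stroma takes precedence because the stromal compartment
overlaps the tumor side (it encircles and disperses between tumor
aggregates). Otherwise the spot goes to the side with the larger marker
score, provided that maximum reaches `min_z` (default 0, i.e. above the
scope mean on the z scale); exact ties go deterministically to the tumor
side. An explicit numeric rule replaces the visual thresholding that a
human would do on spatial feature plots.

# Niches and onion layers

Tumor niches are connected components of tumor-labeled spots under hex
adjacency with at least `min_size = 10` members — an automated replacement
for manual spot circling. The end-to-end pipeline additionally prunes
*pendant* members (fewer than 3 in-niche hex neighbours, iterated): an
isolated mislabeled spot that happens to touch a component would otherwise
corrupt the rim layer and the neighbourhood analysis. Compact aggregates
(hex disks of any radius) are unaffected by the pruning rule.

`concave_hull()` implements the concaveman scheme: start from the convex
hull and dig edges toward the interior point nearest to them whenever the
edge is longer than `concavity` times the candidate's distance to the
nearer edge endpoint (and longer than `length_threshold`). Three
safeguards shape the implementation:

* the candidate is always the point nearest to the edge, which guarantees
  the dug triangle contains no other input point — the polygon always
  contains its input;
* a dig is skipped when the candidate is nearer to an adjacent hull edge
  (locality) or when the new edges would cross the polygon (simplicity);
* among admissible digs the one with the largest length/decision-distance
  ratio is performed first. Because this selection does not depend on the
  concavity threshold, the hull at a larger concavity is an intermediate
  state of the process at a smaller one, making polygon area
  non-decreasing in `concavity` by construction. `concavity = Inf`
  reproduces the convex hull exactly.

Defaults (`concavity = 2`, `length_threshold = 0`) follow the algorithm's
published defaults.

`peel_layers()` stratifies a niche from the rim inward. The default
`hull_peel` mode repeatedly builds the concave hull of the remaining spots
and peels everything within `0.6 × pitch` of the polygon boundary (0.5
would miss staggered rim spots of a hex lattice, 1.0 would take two rows);
it stops when at most 3 spots remain. The grid-native `hex_erosion` mode
peels spots with fewer than six in-niche neighbours. On convex niches the
two agree exactly (a radius-R hex disk gives R+1 layers of sizes 6R,
6(R−1), …, 6, 1); their agreement is itself part of the test suite. Layer
thickness is one peel, so the number of layers is emergent from niche
size rather than fixed.

`layer_profile()` reports the per-layer mean of a score and a trend
statistic: the Spearman correlation between layer index and spot score,
with a two-sided permutation p-value (scores permuted within the niche,
B = 1000, seeded). A constant score is reported as ρ = 0 rather than
undefined; a single layer yields `NA`.

# Neighbourhood correlation

`enriched_spots()` formalizes "elevated" as tier 3 — the top quartile —
reusing the tiering scheme for internal consistency. For each focal spot,
`neighborhood_correlation()` averages the response score over its
ring-≤k hex neighbours (k = 1, the immediate six, by default) restricted
to a mask, and correlates the focal score with that neighbourhood mean
over all focal spots with at least one eligible neighbour (Spearman by
default — robust to the normalization; a permutation p-value with the
response means permuted across focal spots, two-sided, seeded). The
permutation null tests association given the lattice, not spatial
autocorrelation structure.

In the end-to-end pipeline the focal spots are elevated SPP1-mac spots
*outside* the detected niches (a spot inside a tumor aggregate with a high
macrophage score is measuring the aggregate itself), and the neighbour
mask is the detected niche spots, so the response is read only off tumor
cells. These two choices came out of an explicit failure analysis during
design: masking neighbours by the raw tumor-side *label* lets scattered
mislabeled spots act as response carriers, and thinning focal spots by the
stroma label discards information by unrelated noise ranking; both
dilutions are visible on simulated data with planted coupling.

# The synthetic generator

`simulate_visium()` emulates the architecture of a leading-edge slice on a
`grid_rows × grid_cols` pseudo-hex lattice (60 × 120 arrays = 3600 spots
by default): the left half is non-tumor parenchyma expressing a
hepatocyte module; the right half is the tumor side with `n_niches`
compact tumor niches (hex disks of radius 4) expressing a tumor-marker
module; stroma (fibroblast + endothelial modules) fills every tumor-side
spot within `stroma_width` hex steps of a niche or of the interface. The
default width of 15 steps makes the stroma an extended field dispersing
between and around the niches — as at a real leading edge, where stroma
both walls off the interface and encircles tumor aggregates — rather than
a thin capsule. A narrow ring would leave tumor-side spots that express
no module at all; such spots acquire systematically inflated scores under
library-size scaling (their libraries are small, so every gene is scaled
up) and percolate into spurious marker-positive components. Real tissue
has no "empty" spots, and the wide stromal field removes this simulation
artifact. With no niches the stroma simply fills the tumor side.

Counts are negative binomial with `variance = mean + mean²/dispersion`
(dispersion 2, a typical spot-level overdispersion), baseline mean 2 per
gene, and a fold change of 6 on active module genes; 200 background genes
plus 20 genes per module. These effect sizes are testability choices
exposed in `sim_config()`, not biological claims.

Two phenomena are planted with exact ground truth:

* **Rim-to-core proliferation gradient.** Within a niche, proliferation
  genes have mean `baseline × (1 + (fold − 1) · exp(−β(depth − 1)))` with
  depth 1 at the rim and `gradient_beta = 0.5` by default, so the rim is
  the hottest layer, as proliferating tumor cells concentrate near the
  stroma-adjacent rim in real leading-edge tissue.
* **Macrophage–proliferation coupling.** A `triad_fraction = 0.5` subset
  of stroma spots carries the SPP1-mac module with latent strength
  `u ~ U(0, 1)` (expression mean `baseline × (1 + (fold − 1)u)`). Each
  niche spot's proliferation mean is multiplied by
  `fold^(coupling_rho · u_max)` where `u_max` is the largest latent level
  among its adjacent triad spots — a saturating paracrine dose-response,
  monotone in the macrophage signal and exactly the identity when
  `coupling_rho = 0`. The max (rather than a product over neighbours) was
  chosen because stacking per-neighbour boosts confounds each focal
  spot's signal with its competitors' and makes the planted association
  unrecoverable at realistic noise levels.

Determinism: all draws flow from `sim_config(seed=)`; the same config
reproduces byte-identical counts.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: spot deconvolution mixtures (each synthetic
spot is a pure module mixture), UMI saturation, batch and slide effects,
irregular tissue boundaries, and any histology. Results on real slides
additionally depend on signature quality, which the generator sidesteps
by construction.

# Numerical and degenerate-input choices

* Quartile ties go to the lower tier; a constant vector is all tier 0.
* Zero-variance scores: trend and correlation report ρ = 0 / `NA` with a
  warning instead of erroring.
* Spots with zero total counts are dropped (with a warning) at
  normalization.
* Concave hulls require 3 non-collinear points; `peel_layers()` treats
  ≤3 remaining (or collinear) spots as the final layer.
* Permutation p-values use the add-one estimator `(1 + #{|ρ*| ≥ |ρ|}) /
  (B + 1)` and are therefore never exactly zero.
* Signature genes absent from the matrix are dropped with a message (they
  typically come from a different modality); an entirely absent signature
  is an error.

# Problem sizes in the test suite

The acceptance-style tests run the full pipeline at the generator's
default conditions (3600 spots × 320 genes): 100 seeds for the gradient
recovery, 50 coupled plus 400 null seeds for the neighbourhood
correlation and its type-I calibration, and 50 seeds for triad
detectability — a few minutes in total on one CPU. Unit tests use smaller
lattices (24 × 48) where the spec of the check does not fix the default
geometry.

# Known limitations

* The hull-peel boundary tolerance (0.6 × pitch) is tuned to regular hex
  lattices; on heavily distorted coordinates `hex_erosion` is the safer
  mode.
* `find_niches()` cannot separate two niches that touch; they become one
  component (the generator never plants touching niches).
* The neighbourhood permutation test conditions on the focal set; it does
  not correct for spatial autocorrelation of the response field beyond
  the neighbourhood mean construction.
* Whole-slide tiering makes tier thresholds composition-dependent: adding
  large non-tumor areas shifts all quartiles. Use the `scope` argument of
  `tier_quartiles()` when that matters.
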