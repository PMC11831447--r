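# hexniche

Spatial microstructure analysis of the tumor leading edge on Visium-style
hexagonal spot lattices.

At the leading edge — the band around the tumor/normal borderline — tumor
cells aggregate into compact niches encircled by stroma, proliferating
tumor cells concentrate at the niche rim, and SPP1+ macrophages sit in
the stroma next to them. `hexniche` provides the spot-level statistics
needed to quantify this architecture from a spots × genes count matrix
and a spot-position table, for anyone analysing 10x-Visium-like data of
tumor margins:

* **Region partitioning** — tumor side / non-tumor side / stromal
  compartment from marker signature scores (`assign_regions()`).
* **Quartile-tier co-localization** — per-spot signals are tiered into
  quartiles t ∈ {0,1,2,3} and co-localization of two or three signals at
  a spot is the product t₁t₂(t₃): 0 when any signal is absent, maximal
  (9 or 27) when all are in their top quartile (`tier_quartiles()`,
  `coloc()`). The same density × intensity product logic scores IHC
  staining on the 1–16 scale (`ihc_score()`).
* **Onion layering** — tumor niches are detected as hex-connected
  components, peeled into rim-to-core layers by iterated concave hulls
  (concaveman scheme, `concave_hull()`) or hex erosion, and profiled per
  layer with a Spearman trend test of score vs. layer depth
  (`find_niches()`, `peel_layers()`, `layer_profile()`).
* **Hex-neighbourhood correlation** — for focal spots with an elevated
  signal (top-quartile SPP1-mac score), the response (proliferation
  score) is averaged over their ring-k hex neighbourhoods and correlated
  with the focal signal, with a permutation p-value
  (`enriched_spots()`, `neighborhood_correlation()`).

Signature scores are per-spot means of scaled, centered (z-scored)
expression over a gene set (`module_score()`), after median-library
scaling and log1p normalization (`normalize_counts()`).

Because leading-edge patient data are rarely public, the package ships a
synthetic Visium generator (`simulate_visium()`) that plants the whole
architecture — niches, stromal field, triad spots, a rim-to-core
proliferation gradient with per-layer decay exp(−β·(depth−1)), and a
macrophage→proliferation coupling fold^(ρ·u) — with exact ground truth,
negative-binomial counts (variance = μ + μ²/θ), and full determinism per
seed.

## Worked example

```r
library(hexniche)

sim <- simulate_visium(sim_config(seed = 1))
print(sim)
fit <- leading_edge(sim$counts, sim$spots, sim$signatures, seed = 1)
print(fit)
print(fit$profiles[[1]])
```

```
Synthetic Visium dataset: 3600 spots x 320 genes
region
non_tumor_side         stroma     tumor_side
          1800           1617            183
183 niche spots in 3 niche(s); 808 triad stroma spots
Leading-edge microstructure analysis
  spots: 3600  regions: tumor_side=318 non_tumor_side=1797 stroma=900 unassigned=585
  niches detected: 3 (sizes 64, 61, 61)
  proliferation vs layer depth: rho = -0.835 (perm p = 0.000999)
  SPP1-mac vs neighbour proliferation: spearman rho = 0.432 (perm p = 0.005994), 42 focal spots
 layer n_spots mean_score
     1      26  1.8815367
     2      19  1.3650899
     3      12  1.1046615
     4       6  0.7565254
     5       1  0.4477137
trend: Spearman rho = -0.713, permutation p = 0.000999
```

Reading the output: the three planted niches are recovered as three
tumor-side components; the proliferation score falls monotonically from
the outermost onion layer (mean z ≈ 1.88) to the single core spot
(≈ 0.45), with a strongly negative layer trend — the rim proliferates,
the core does not. The SPP1-mac signal of the 42 elevated focal spots
correlates positively (ρ = 0.43) with the proliferation of their in-niche
hex neighbours, recovering the planted macrophage–tumor coupling. On the
null generator (`coupling_rho = 0`) the same test rejects at the nominal
5% rate.

`plot(fit)` draws the spot map coloured by region with focal spots
circled; `plot(fit, which = "layers")` shades niches by onion-layer
depth. A one-command run over a flat key=value config — simulate (or
read real Visium inputs), score, tier, partition, layer, co-localize,
correlate, and write every stage as TSV plus a JSON manifest — is
`run_all("run.cfg", "out/")`.

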