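---
title: "Models and methods in landplus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in landplus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landplus)
```

`landplus` couples a top-down demand model with a bottom-up spatial
allocator and a valuation layer. This vignette documents the models, the
choices made where the design was genuinely open, and what the synthetic
test-bed does and does not establish about real landscapes.

## The land-demand model

The demand model treats a county as a closed system of stocks advanced by
explicit annual Euler steps (one-year step, no sub-annual dynamics):
total population, urban population and GDP each grow by a scenario rate,
`x_t = x_{t-1}(1 + r)`. Fixed-asset investment is closed as
`INVEST_t = rho * GDP_t`; the causal structure of county land systems
links investment and urbanization to construction land, and a
proportional closure is the simplest one consistent with that structure.
Construction-land demand is the linear form

$$\mathrm{SCON}_t = \mathrm{SCON}_{t_0} + c_u\,\mathrm{URPOP}_t +
c_i\,\mathrm{INVEST}_t,$$

with defaults $c_u = -3.35\times10^{-5}$ km²/person and
$c_i = 5.727\times10^{-6}$ km² per investment unit, clamped at zero. We
apply it in *increment form*: the anchor is chosen so the base-year state
reproduces the observed base-year construction area exactly, and growth
comes from the increments of its drivers. The monetary unit of
investment is deliberately configurable — the coefficient $c_i$ is only
interpretable jointly with a unit choice, so the default base GDP is
expressed in a unit (1e4 yuan) that makes the implied investment scale
plausible for a county of this size.

Two parameters close gaps that no printed equation fixes:

* **`investGdpRatio`** defaults to a closed-form calibration such that
  the low-growth scenario (8 %/yr GDP, 0.22 %/yr population) reaches a
  2035 construction demand of 191.58 km². Since demand is linear in the
  ratio, the calibration is exact and involves no search.
* **`donorWeights`** say where construction growth comes from:
  cultivated 0.35, forest 0.45, water 0.12, grassland 0.08, other 0.10,
  and garden −0.10 (a credit: garden land expands with the planting
  industry). The weights sum to 1, so total area is conserved to 1e-6 km²
  over any trajectory. When a donor is exhausted it is clamped at zero
  and the remaining positive weights are renormalized, with one warning
  per run. This donor closure is a declared approximation of the
  unpublished full equation set of such models, chosen because it
  conserves area and reproduces the qualitative signs (construction and
  garden up, forest/water/cultivated down, grassland to ~0 under fast
  growth).

Validation arithmetic uses the printed-table convention
`|sim - hist| / hist * 100`, with pass thresholds of 1 % (population,
cultivated, forest) and 2 % (construction). `fitSDCoefficients` recovers
$c_u, c_i$ by ordinary least squares with an intercept absorbing the
anchor; a constant regressor is reported as unidentifiable rather than
silently dropped.

## The allocator

**Expansion analysis.** Cells newly converted to class *k* between the
two dated maps are positives; an equal number of unchanged cells are
negatives (balanced sampling — the alternative, proportional sampling, is
not stated in the sources that describe the strategy, and balanced
classes are the safer default for rare transitions). One random forest
per class (`ranger`, 100 trees, unlimited depth, impurity importances,
single-threaded for reproducibility) yields a development-potential
surface in [0, 1] at every cell and per-driver contribution scores
normalized to sum to one. Classes with under two positives or negatives
— or none at all — get a flat 0.5 surface and NA contributions, with a
warning: a flat surface encodes "no information", not "no conversion".

**Allocation.** Demands in km² are converted to cell counts by half-up
rounding and then reconciled twice: the counts are adjusted by largest
remainder to partition the map exactly, and no class's target may fall
below its restricted-cell count, because restricted cells cannot change
class under any seed — a smaller target would be infeasible for *any*
allocator, so the excess is debited from classes with slack. Each sweep,
every under-target class scores its candidate cells (donor class above
target, legal transition, unrestricted): cells touching an existing
patch score `P * w * N` with `N` the windowed class density (3×3 Moore
window by default; window size is unstated in the sources, 3×3 is the
common default); cells with zero neighbourhood effect can only enter as
seeds, accepted when `P >= threshold * u` with `u ~ U(0,1)` — i.e.
Monte-Carlo acceptance proportional to potential. Seeds score `P`
itself, so fresh seeds compete with patch growth. Candidates convert
highest-score-first (ties broken by seeded random keys) while demand and
donor supply last; the threshold of every unmet class then decays by
0.9 per sweep (initial threshold 1), progressively admitting lower-
potential seeds. Setting the initial threshold to 0 and the
neighbourhood weights to 0 removes all randomness: allocation reduces to
deterministic ranking by potential, which is the oracle the tests
enumerate against. Demand is always met to within one cell per class
when feasible; an iteration cap (default 1000 sweeps) returns the best
map plus an unmet-demand report rather than failing.

## Valuation

One equivalent is `grain yield x grain price / 7` yuan/ha — the
divisor-7 convention of equivalent-factor practice is a default, not
hard-coded. The shipped coefficient table (9 services × 7 land types,
construction all zero) is audited on load: column sums must agree with
the table's total row to 0.025 yuan/ha, which catches transcription
errors while tolerating the drift of tables whose rows were rounded
independently. Totals are computed from the service-row sums so that the
matrix marginals are exactly consistent; at the two-decimal display
convention (10^8 yuan, half-up) both conventions print identically.
Percent changes against a zero baseline are reported as NA, never
Inf.

## Spatial statistics

Zone adjacency is derived from the rasterized partition: rook = some
cell pair shares an edge, queen (default) adds corners; weights are
row-standardized. The sources name neither the weights scheme nor the
hot/cold procedure, so the defaults are the standard choices for
village-polygon analyses: queen contiguity, Moran's I with a 999-
permutation two-sided pseudo p (observed arrangement counted), analytic
normal p alongside, and Gi* with self-included weights labelled at
|z| = 1.65/1.96/2.58. Both statistics are verified against double-loop
brute-force oracles to 1e-12, and the permutation test's size is checked
to be near-nominal under an independence null.

## The synthetic test-bed

`generateLandscapePair` places each configured (from, to) transition on
the top-ranked eligible cells of a linear driver score (standardized
layers, configurable effect sizes, seeded tie-breaks). Deterministic
ranking makes transition counts *exact* and recovery tests sharp, at the
cost of a harder-edged driver footprint than a logistic sampling scheme
would leave. Drivers are Gaussian noise smoothed to a configurable
bandwidth; zones are Voronoi cells of random seeds (contiguous,
irregular, village-like); restriction masks are uniform random draws.
Socio-economic histories are generated by the demand model itself plus
independent Gaussian noise, so the zero-noise history is reproduced
bit-for-bit by the forward run.

What passing tests show: the bookkeeping (transition counts, mass
balance, restriction conservation), the estimators (coefficient
recovery, dominant-driver recovery in ≥95 % of replicates), the
closed forms (Moran's I = −1 on a checkerboard, kappa arithmetic) and
end-to-end determinism all hold. What they do not show: real landscapes
have autocorrelated, non-Gaussian drivers, patch-structured land
mosaics rather than i.i.d. class layouts, and policy-driven
restrictions; hindcast accuracies near 0.98 kappa on synthetic scenes
say nothing about accuracy on real data, and the county-scale published
figures (hindcast 97.69 %/kappa 0.96, zonal Moran's I 0.2225, the exact
2035 areas) require the original rasters and the unpublished demand
equations, so the package checks their *orderings and analogues*
instead.

## Problem sizes and numerical conventions

The default test-bed uses 50×50–100×100 grids at 10 m cells, 12–25
zones, 100 trees per forest, 999 permutations, 25–100 property-test
replicates — sizes chosen so the whole suite exercises every code path
in well under a minute while keeping the statistical checks (≥95 %
recovery rates, permutation size in [0.02, 0.09]) adequately powered.
Conventions fixed package-wide: class codes 1 cultivated, 2 grassland,
3 forest, 4 water, 5 garden, 6 construction, 7 other, 0 nodata;
row-major north-up grids with square cells; areas = cells ×
cellSize²/1e6 km² (×100 to ha); display rounding half-up to two decimals
in 10^8 yuan; seeds derived per stage by a counter scheme so adding a
stage never perturbs earlier streams.

## Known limitations

The donor-weight closure is an approximation, not a reconstruction of
any published equation set; the investment unit is conventional; the CA
has no explicit patch-size distribution (patches emerge from the
neighbourhood feedback); zone GeoJSON stores cell-square multipolygons
rather than dissolved boundaries; and the permutation test treats zones
as exchangeable, which mildly overstates significance for strongly
heterogeneous zone sizes.
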