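---
title: "Methods: models, rules and numerical choices in onca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, rules and numerical choices in onca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(onca)
```

`onca` chains five analysis stages — suitability post-processing,
occupancy delineation, abundance estimation, unit prioritization and
least-cost connectivity — into one reproducible pipeline for assessing a
large carnivore's population status. This vignette documents the models
behind each stage, the tunable parameters with their defaults and units,
the behaviour of the synthetic-data generators, and the numerical and
design choices that were genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Suitability post-processing

The package consumes a finished continuous suitability surface in
`[0, 1]`; fitting such a surface (Maxent or otherwise) is explicitly out
of scope. Settings occasionally reported alongside such models (e.g. a
1e-5 convergence threshold with 500 iterations) are provenance for the
input, not behaviour of this package.

**Spatial thinning** (`thin_records()`) retains one record per grid cell
of area `cell_area_km2` (default **144 km²**, a female home-range-sized
cell; side 12 km), selected uniformly at random. It removes
pseudo-replication when many records belong to one individual.

**Threshold selection** (`select_threshold_max_ss()`) maximizes
sensitivity + specificity over candidate thresholds: midpoints between
adjacent distinct pooled scores plus {0, 1}. Ties take the smallest
maximizer. Sensitivity counts presences `>= t` (a record exactly at the
threshold is *suitable* — the boundary convention is pinned by tests).

**Reclassification** (`reclassify()`) uses half-open classes
`[lo, hi)` with the top class closed at 1: unsuitable `< t`, marginal
`[t, 0.5)`, medium `[0.5, 0.75)`, high `[0.75, 1]`. The canonical bounds
assume `t < 0.5`; on arbitrary synthetic surfaces the data-driven
threshold can exceed 0.5, in which case the pipeline re-derives
equal-width bounds over `(t, 1]` (`adapt_class_bounds()`) so that the
four-class scheme stays well formed.

**Evaluation** (`evaluate_suitability()`, `suitability_report()`): AUC is
the Mann–Whitney rank statistic `P(presence > background) + ½P(tie)`
against a seeded uniform background sample (default **10,000** cells);
its spread comes from `n_replicates = 10` independent 70/30 train/test
re-draws. "Cross-validation with replacement" is ambiguous between
independent re-draws and bootstrap; independent re-draws are the default
and `bootstrap = TRUE` switches to out-of-bag evaluation. The omission
rate is the fraction of test records below the threshold; significance is
the one-sided binomial probability of at least the observed number of
suitable-cell hits when the success probability equals the suitable
fraction of the non-NoData area (the extrinsic omission form).

## 2. Occupancy

Suitable cells intersected by a road polyline become barriers (roads are
rasterized by dense sampling at quarter-cell steps; vector splitting was
rejected as fragile on sliver geometries). Remaining suitable cells are
grouped into **4-connected** components: 8-connectivity would let
fragments leak across a diagonal road crossing, and the choice is pinned
by an L-shaped test fixture.

A fragment is **AJO** (occupied) when a record lies inside it or strictly
closer than `radius_km` to its boundary; a record-free fragment is
**APJO** when strictly closer than `radius_km` to an AJO fragment,
determined after all AJO labels are fixed — APJO status does not chain.
"Closer than" is strict inequality throughout; distances are Euclidean
point-to-cell-square (exact for cell-union fragment geometry) in planar
km. The default radius is the **median distance of outside records to
their nearest fragment** (`median_outside_distance()`), computed over all
outside records; 1.7 km is the configured fallback when no record falls
outside. At radius 0 the rule reduces to containment and the APJO set is
empty; enlarging the radius never shrinks the AJO set (both tested).

## 3. Abundance

### Spatially explicit capture–recapture

The Bayesian data-augmentation formulation with a Bernoulli encounter
model (the SPACECAP default):

* `z_i ~ Bernoulli(psi)` for `i = 1..M` (augmented super-population),
* activity centres `s_i` uniform over the state space — a rectangle
  around the trap hull with buffer `state_space_buffer_km` (default
  **15 km**), optionally restricted to suitable cells of a habitat mask
  discretized at `state_space_cell_km` (default **1 km**),
* `y_ijk ~ Bernoulli(z_i p_ij)` per occasion, with the half-normal
  `p_ij = p0 exp(-d_ij^2 / (2 sigma^2))`,
* flat priors: `p0, psi ~ U(0,1)`, `sigma ~ U(0, sigma_max)` with
  `sigma_max` half the state-space diagonal by default.

The sampler (Rcpp) is Metropolis-within-Gibbs: random-walk MH for `p0`,
`sigma` and the centres of real individuals; Gibbs draws for the
inclusion indicators of undetected individuals, for `psi`
(Beta-conjugate), and for the centres of excluded individuals (uniform
prior). Defaults: `M = max(4n, 50)`, **52,000** iterations, **2,000**
burn-in, thinning **10**; tests and the acceptance script shorten chains
to 8,000/2,000/5, which pilot runs showed to give indistinguishable
posterior summaries at these data sizes. Convergence is reported as
Geweke z-scores (first 10% vs last 50%, AR-spectral variance); |z| < 1.96
is the advisory gate. Density is `NSuper / |state space| * 100` with the
suitable-cell area as denominator when a mask is supplied. Cubs and
individuals of undetermined age are excluded before fitting; sex is
recorded but not modelled (pooled detection parameters).

Preconditions mirror survey usability: at least `min_individuals`
(default **6**) distinct adults, and at least one spatial recapture —
without one, `fit_secr()` aborts and recommends the non-spatial path.

**What a green recovery test establishes.** The reference simulation
(density 1 / 100 km², `p0` 0.1, `sigma` 2 km, 60 occasions, 7×7 traps at
2 km) realizes `N ~ Poisson(7.84)` animals of which typically 2–8 are
detected. Because `NSuper` estimates the *realized* population in the
state space, credible-interval coverage is evaluated against each
replicate's realized density, while bias is measured against the nominal
density (process noise averages out across 50 replicates). Replicates
realizing fewer than two detectable animals cannot be fitted and are
skipped, exactly as such surveys are unusable in the field. Measured at
seed 1: |bias| ≈ 6% and coverage 94% over 50 replicates.

### Jackknife Mh fallback

For surveys whose individuals were never recaptured across stations, the
Burnham–Overton jackknife estimators of orders 1–5 are computed from the
capture-frequency vector; order is selected by the sequential chi-square
test on successive differences (first non-significant at alpha 0.05).
Program CAPTURE additionally interpolates between adjacent orders; that
exact formula is not available and the selected-order estimate is
returned instead. The reported `N_hat` is clamped at the observed count
`S` (higher-order estimates can mathematically dip below `S`). The
coefficients are cross-checked in the tests against an independent
generalized-jackknife derivation (drop-j occasion resampling).

The **effective sampled area** is the union of per-trap discs of radius
`buffer_km` (the mean home-range radius, e.g. 5.8 km), integrated on a
fine grid with step `buffer_km / 500`, which keeps the discretization
error of a disc below 0.1%.

## 4. Prioritization

Occupied (AJO/APJO) fragments are grouped by **single-linkage**
clustering at boundary distance < `grouping_radius_km` (default
**15 km**, the radius of the largest home range) — single linkage because
the grouping rule is pairwise ("less than 15 km from a fragment with
presence"). `forced_merges` joins listed pairs regardless of distance,
for units managed jointly despite separation.

Classification rules (`classify_unit()`):

* both sexes confirmed → **JCU**; Type I when the population point
  estimate ≥ `pop_threshold` (default **50** adults) *or* when the
  capacity rule holds: `ajo_km2 × reference_density / 100 ≥ 50`. The
  capacity rule operationalizes the qualitative "habitat large enough to
  hold a larger population" override; `reference_density_per100km2`
  defaults to **1.0**, close to the median of observed camera-trap
  densities (the bundled survey table's median is 1.2). Either reading of
  "estimated population size" (point estimate or capacity) yields the
  same reference classification, which is why the ambiguity is tolerable.
* both sexes not confirmed → **PJCU** when good-condition (medium+high)
  habitat ≥ `good_area_threshold_km2` (default **230 km²**, the good
  habitat of the smallest reference JCU — a data-derived constant exposed
  as config), else **small fragment**.
* record-free fragments → **expansion** when < 15 km from a JCU/PJCU,
  else **core** when contiguous good habitat ≥ 230 km², else other.

`aggregate_population()` sums `(point, low, high)` component-wise over
units carrying estimates. Recommendations are a static lookup from label
(+ isolation flag) to management templates.

The bundled evidence table (`inst/extdata/af_unit_evidence.csv`) encodes
the reference bookkeeping of 13 units. Good-condition areas per unit are
not published; the table backfills them with the AJO area as a flagged
proxy, except the aggregate small-fragments row where that proxy would
contradict the row's definition (member fragments each hold < 230 km² of
good habitat) — there a synthetic 100 km² is used and marked in the
fixture header.

## 5. Connectivity

Resistance is the **linear** inverse of suitability,
`r = 1 + (1 - s)(r_max - 1)` with `r_max = 100` by default; the
reciprocal form `1/s` is available but explodes near zero suitability,
which is why linear is the default. NoData cells get `r_max`. The actual
transform used by any given study is rarely reported; consequently the
testable output is relative ranking and oracle-checked geometry, not
absolute cost values.

Cost distance runs Dijkstra on the 8-neighbour cell graph with edge
weight = mean of endpoint resistances × cell size (×√2 on diagonals) —
the common cost-distance convention. Pairwise linkages take the minimum
accumulated cost between any member-cell pair and report one
representative least-cost path; units sharing or bordering cells have
cost 0. Network pruning to adjacent cores and corridor-width mapping (as
in Linkage Mapper) are not reproduced. Tests pin equality with a dense
independent shortest-path oracle on grids up to 30×30 (tolerance 1e-9),
the lower bound `cost ≥ r_min × Euclidean distance`, and monotonicity
under resistance increases.

## 6. Synthetic data: what it emulates, what it does not

`generate_landscape()` produces a Gaussian random field (FFT convolution
of white noise with a Gaussian kernel of standard deviation
`autocorrelation_range_km`, on a padded grid to avoid wrap-around),
min–max rescaled to `[0, 1]`, plus low-curvature edge-to-edge roads.
`sample_presences()` draws cells proportional to suitability and jitters
within the cell. `simulate_secr()` places `N ~ Poisson(D·A/100)` animals
(or exactly `fixed_N` for exact-recovery tests) uniformly and detects
them under the half-normal model. All generators are pure functions of
(spec, seed); RNG state is saved and restored around every draw.

The generators emulate autocorrelated habitat, road-bisected fragments,
records concentrated in suitable cells, and realistic capture sparsity.
They do **not** emulate real land-cover classes, deforestation dynamics,
record reporting bias, trap-shyness/attraction, or sex-specific movement
— so a green pipeline run certifies the arithmetic and the rules, not the
realism of any particular ecological inference. Region-wide headline
figures from real geodata (tens of thousands of km² of occupancy) are not
reproducible at desk scale; the acceptance suite instead pins the
published internally consistent arithmetic (unit-table totals, occupancy
shares, class counts) plus oracle equivalences.

## 7. Degenerate inputs and numerical details

* The >= 3σ state-space margin is enforced only for auto-built trap
  grids; explicit trap layouts may violate it (needed for the
  large-sigma limit case, where the margin requirement is unsatisfiable).
* `simulate_secr` with `p0 → 0` returns a zero-individual capture set;
  `fit_secr` on it fails fast.
* Posterior mass at `NSuper = M` (more than 1% of retained samples within
  1 of `M`) triggers a warning advising a larger augmentation.
* ASCII grids are written at full double precision (`%.17g`), so write →
  read round trips are bit-faithful and pipeline reports are
  byte-identical across reruns with the same config and seed.
* All fragment/unit distances are exact rectangle-to-rectangle distances
  between cell squares, not centre-to-centre approximations.

## Known limitations

* Maximum-likelihood SECR, open-population models and sex-specific
  detection are out of scope; the Bernoulli encounter model is the only
  observation model.
* The occupancy stage is deterministic presence-based labelling, not
  detection-corrected occupancy modelling.
* Threat elicitation is reduced to a static recommendation lookup.
* GeoTIFF I/O is unavailable in this environment; the ASCII grid format
  carries the same information for planar-km workflows but has no
  embedded CRS metadata.
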