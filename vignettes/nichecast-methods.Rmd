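---
title: "Methods: presence-only niche modelling and scenario projection in nichecast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only niche modelling and scenario projection in nichecast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecast)
```

`nichecast` re-implements, as one coherent pipeline, the bioclimatic
conservation assessment workflow used for wild arabica coffee: from raw
georeferenced occurrence records through a maximum-entropy niche model
to locality- and area-level climate-change accounting. This vignette is
the package's own account of the methods: what each stage computes, the
assumptions baked in, the parameters that matter, and where design
choices were genuinely open.

## 1. Occurrence cleaning

Raw records carry a positional confidence expressed as the diameter (km)
of a circle around the stated coordinate. Cleaning is a fixed chain:

1. **Confidence filter** (`filter_records()`): records with no usable
   coordinates are rejected (`no_georeference`), as are records whose
   confidence diameter strictly exceeds 5 km (`low_precision`) — the
   scale above which a record cannot be placed within a ~5 arc-minute
   cell. The boundary is kept: exactly 5 km passes.
2. **Deduplication** (`deduplicate()`): one locality per distinct
   coordinate pair after rounding to 4 decimal places (~11 m). Four
   decimals is finer than any stated confidence, so rounding never
   merges genuinely distinct field sites; the precision is an argument
   for data recorded otherwise.
3. **One per cell** (`one_per_cell()`): at most one locality per
   modelling-grid cell, retaining the first in input order. First-seen
   retention is arbitrary but deterministic; with sorted input it is
   reproducible, and the retained sample is a spatial thinning, not a
   quality ranking.
4. **Distance thinning** (`thin_min_distance()`): greedy retention in a
   seeded random visit order until all pairwise separations are at
   least 0.2 degrees. Distances are planar degrees, matching the
   degree-based separation criterion this workflow historically used,
   not great-circle km. Greedy thinning is maximal for its visit order
   but makes no claim of being the largest feasible subset.

The clustering diagnostic (`nearest_neighbour_index()`) is the
Clark–Evans ratio R of observed to expected mean nearest-neighbour
distance. R is reported in its textbook uncorrected form; the z score,
however, uses the Donnelly edge-corrected expectation and variance.
Numerically the uncorrected normal approximation over-calls dispersion
badly on bounded rectangles (about 15% false "dispersed" verdicts on
simulated complete spatial randomness with n = 500, against a nominal
5%), while the corrected test is near-calibrated (~94–95% "random"
verdicts). Classification is two-sided at |z| = 1.96.

## 2. The maximum-entropy niche model

The model is the standard presence-background Gibbs distribution. With
features `f` built from the environmental variables (rescaled to [0,1]
by their training bounds), the background distribution is
`P(x) = exp(λ·f(x))/Z`, and fitting maximises the L1-penalised presence
log-likelihood. The penalty scale per feature is its presence standard
error `s_f = sd_presence(f)/√m`, floored at `0.05/√m` so near-constant
features keep a workable bound rather than becoming hard moment
constraints (which stall the optimiser without changing the fit
meaningfully). At the optimum every feature satisfies
`|E_model[f] − mean_presence[f]| ≤ β·s_f`; the package asserts this
after every fit and stores the worst residual in the model object.

Design choices, and why:

- **Feature classes**: linear + quadratic + product + hinge (5 interior
  knots per variable), the auto-feature choice mature maxent tooling
  applies at this sample size. All features live in [0,1].
- **Optimiser**: L-BFGS-B on the split form λ = λ⁺ − λ⁻ with
  non-negativity bounds, which makes the L1 penalty smooth; gradient
  tolerance 1e−6, up to 500 iterations with warm restarts. Any convex
  optimiser would do; this one needs no extra dependency.
- **Regularisation**: β = 1 uniform across feature classes. Per-class β
  tables are deliberately out of scope.
- **Background**: 10,000 (default; configurable) uniform seeded
  non-nodata cells — presence-background, never presence-absence.
- **Logistic output**: `p = e^H·raw/(1 + e^H·raw)` with H the entropy
  of the fitted background distribution, so raw = e⁻ᴴ maps to 0.5.
  Logistic scores are what all thresholds and classifications consume.
- **Projection beyond training bounds clamps** rather than
  extrapolates: under a no-migration reading of future suitability,
  letting quadratic or hinge terms extrapolate into unobserved climate
  is the riskier default.

Evaluation (`evaluate_model()`) holds out 20% of presences (seeded
split), reports train/test AUC against the background by the exact
rank-sum identity (ties 0.5), permutation importance (mean training-AUC
drop over 5 reshuffles per variable, clamped at zero and normalised to
100%), and jackknife gains from with-only / without refits per
variable, where gain = log(n_background) − H.

## 3. Thresholds and classification

With present-day logistic scores at all n unique localities, the cutoff
for level ℓ ∈ {0.68, 0.95, 1.00} is the score of the k-th highest
locality, k = ⌈ℓ·n⌉. For n = 349 this yields k = 238 at the 68% level —
the quantile convention is chosen precisely because it reproduces that
published baseline count by arithmetic. Classification into disjoint
bins uses strict `>` at the optimal and intermediate cutoffs (matching
cutoffs printed as "(>0.564)") and `≥` at the marginal cutoff, so every
training locality is suitable at baseline. Two consequences are worth
stating plainly:

- the locality sitting exactly on a cutoff falls in the class below it,
  so the strictly-above optimal count at baseline is k − 1 when scores
  are distinct;
- when massive ties collapse adjacent cutoffs to one value, a score
  equal to that shared cutoff belongs to the *higher* class, so a
  constant score vector classifies as all-optimal, not all-marginal.

Tie counts that make a level exactly unattainable are recorded in the
threshold object (`attained` vs `target_k`) rather than silently
adjusted.

## 4. Locality analysis, area analysis, core localities

**Locality analysis**: each unique locality is looked up on every
scenario × date logistic surface by nearest cell center (half-open
convention: a point on a cell edge belongs to the north-west cell, row
1 is north), classified, and counted into a class × scenario × date
table whose columns each sum to n minus any localities flagged on
nodata. Raw score trajectories are retained for histograms (40 equal
bins on [0,1]).

**Area analysis**: each surface is reclassified per cell, then the
no-migration ("no-gain") mask forces cells unsuitable at baseline to
stay unsuitable at all future dates — future suitable area is always a
subset of baseline suitable area. The stricter ratchet (class at a
later date can never exceed the class at an earlier date within a
scenario) is an explicit flag, off by default: no-gain is a stated
method assumption, while full threshold exclusivity is an
interpretation caveat, so both behaviours are exposed and tested. Cell
areas use the cosine-latitude correction at each row's center. Percent
change is reported against the baseline *cumulative* area at the same
threshold level; on a clipped study region relative change is the
meaningful quantity.

**Core localities**: per locality, the sum (and standard deviation) of
logistic scores across all surfaces *including baseline*. No published
numeric criterion for "core" exists, so the default is the top decile
by total — explicitly an interpretation, configurable — with ties
broken by lower standard deviation, then id. The protected-area overlay
is an even-odd ray-casting point-in-polygon test (boundary counts as
inside) against GeoJSON polygon rings; holes are rejected rather than
mishandled.

## 5. The synthetic-data module

The generator defines the study conditions under which the pipeline is
tested; it is deliberately simple and fixed:

- **Landscape**: four bioclim-like layers (temperature seasonality,
  warmest-quarter temperature, driest-month precipitation,
  wettest-quarter temperature — the strongest predictors in highland
  coffee niche models), each Gaussian-kernel-smoothed white noise
  (autocorrelation length 5 cells by default) plus a deterministic
  north–south gradient, rescaled to realistic means and spreads (e.g.
  warmest quarter 22 ± 2.5 °C).
- **True niche**: a product of Gaussian bells. The default is a
  *montane specialist*: optimum at the cool, stable, moderately moist
  end of the landscape and tolerances of roughly half a layer standard
  deviation, giving mean true suitability ≈ 0.03 and ~1% of cells above
  0.5. A narrow endemic — not a generalist — is the realistic analogue
  for this workflow's target species, and it is what makes
  high-discrimination evaluation meaningful (the best achievable
  presence-background AUC on this landscape is ≈ 0.95; a broad
  generalist niche caps AUC near 0.8 regardless of model quality).
- **Scenarios**: additive warming on temperature layers, multiplicative
  drying on precipitation, additive shift on seasonality. Defaults:
  +1/+2/+3 °C at 2020/2050/2080 for the strongest scenario, scaled by
  0.9 and 0.7 for the two milder ones; drying factor 1 − 0.05·ΔT;
  seasonality +2·ΔT. Values are invented but conventional in magnitude,
  and configurable. Warming is monotone with date, so the true niche
  loses suitability monotonically within every scenario.
- **Delta downscaling stand-in**: coarse anomalies are interpolated
  bilinearly (not thin-plate-spline) to the fine grid, added to
  temperature and multiplied into precipitation — adequate to exercise
  the pipeline contract; a TPS interpolator would be a drop-in
  extension.
- **Occurrence sampling**: presences drawn with probability
  proportional to true suitability, optionally through a
  parent–offspring cluster process mimicking survey effort; a fraction
  of records is made rejectable (missing coordinates or confidence
  diameter over 5 km) and exact duplicates are injected. A separate
  fixture builder (`make_survey_fixture()`) reproduces the historical
  cleaning-count structure 719 raw → 713 accepted → 349 unique
  localities → 197 one-per-cell samples exactly, by construction.

What passing tests on this generator do **not** show: real spatial
sampling bias (roads, reserves), non-Gaussian niches, interactions
between climate variables beyond what product features capture,
vegetation or land-use change, or GCM physics. Results on synthetic
data validate the machinery and its invariants, not ecological claims
about any real species.

## 6. Numerical choices and degenerate inputs

- Grids are matrices with `NA` as the nodata mask; all arithmetic
  propagates nodata, class grids are masked wherever baseline is
  nodata, and localities on nodata are flagged and excluded from counts
  rather than dropped silently.
- ESRI ASCII grid is the raster exchange format (plain text, 9
  significant digits); model objects serialise to JSON and round-trip
  predictions exactly.
- AUC uses the rank-sum identity — exact, including ties — rather than
  trapezoid integration.
- Constant features are dropped with a warning before fitting;
  non-convergence (optimiser failure *and* a box-constraint residual
  above 1e−4) is an error carrying the residual, never a silent
  degraded fit.
- All randomness (landscape, sampling, splits, thinning order,
  background) is seed-controlled; identical seeds give byte-identical
  pipeline CSVs.
- Problem sizes used by the test suite and the acceptance script —
  50–100-cell-square landscapes, 200–600 records, 1,500–2,000
  background points — were chosen as the smallest sizes at which the
  statistical properties under test (recovery correlation, AUC,
  calibration of the clustering test) are stable across seeds.

## 7. Known limitations

- The maxent re-implementation targets the documented model family
  (features, L1 box constraints, entropy-pivot logistic output), not
  bit-compatibility with any particular release of the reference tool.
- Greedy thinning and first-seen cell retention are order-dependent
  heuristics; both are seeded and documented, neither is optimal.
- The locality/area accounting assumes co-registered grids throughout;
  reprojection between coordinate systems is out of scope.
- The end-to-end pipeline runs on a single core; landscapes far beyond
  ~10⁶ cells would want a streaming raster backend.
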