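# nichecast

Presence-only ecological niche modelling and bioclimatic projection
under emission scenarios, packaged as a tidy, fully testable pipeline.
`nichecast` implements the conservation-assessment workflow developed
for indigenous (wild) *Coffea arabica* in the Ethiopian highlands:
clean georeferenced occurrence records, fit a presence-background
maximum-entropy niche model, derive locality-quantile suitability
thresholds, project suitability onto scenario × date climate stacks,
and score candidate "core localities" for long-term in-situ
conservation. It is aimed at conservation biogeographers and SDM
practitioners who want the whole chain — including its sampling-bias
handling and no-migration accounting — as inspectable, reusable code.

Because the original field localities are unpublished and the climate
rasters are external downloads, the package ships a first-class
synthetic-data module: spatially autocorrelated bioclim-like layers,
scenario-specific warming/drying deltas, a known Gaussian ("true")
niche, and clustered occurrence sampling with injected bad records.
Every downstream stage is tested against this known ground truth.

## The model

Given presence samples and a uniform background drawn from the
landscape, the niche model is the Gibbs distribution over background
cells

    P(x) = exp(λ·f(x)) / Z

with features f(x): linear, quadratic, pairwise-product and hinge
expansions of the (0–1 rescaled) environmental variables. The weights λ
maximise the L1-penalised presence log-likelihood

    mean_presence[λ·f] − log Z − β Σ_f s_f |λ_f|,

where `s_f = sd_presence(f)/√m` is the feature standard-error scale. At
the optimum every feature satisfies the box constraint
`|E_model[f] − mean_presence[f]| ≤ β s_f`. Suitability is reported on
the logistic scale `p = e^H raw / (1 + e^H raw)` with H the entropy of
the fitted distribution, so a typical presence cell scores 0.5.

Thresholds follow the locality-quantile convention: with n training
localities and levels 0.68 / 0.95 / 1.00, the cutoff at level ℓ is the
score of the k-th highest locality, k = ⌈ℓ·n⌉, defining disjoint
optimal / intermediate / marginal / unsuitable classes. Projection onto
future stacks clamps variables to their training range, and the area
analysis applies a no-migration rule: cells unsuitable at baseline stay
unsuitable at every future date (optionally a stricter ratchet forbids
any class improvement through time).

## Worked example

```r
library(nichecast)
library(dplyr)

spec  <- grid_spec(100, 100, cell_size = 0.01,
                   origin_lon = 35, origin_lat = 9)
base  <- generate_baseline(spec, seed = 1)
truth <- true_suitability(base, default_niche())
recs  <- sample_occurrences(truth, spec, 600, seed = 2)

prep <- prepare_occurrences(recs, spec)
c(nrow(prep$accepted), nrow(prep$localities), nrow(prep$samples))
#> [1] 594 417 334      # accepted -> unique localities -> 1-per-cell samples

vars <- names(base$layers)
bg   <- background_sample(base, 2000, seed = 3)
pres <- extract_at(prep$samples[c("lon", "lat")], base)
m    <- fit_maxent(pres[vars], bg[vars], beta = 1)
glance(m)
#>   n_presence n_background n_features n_active entropy  beta l1_norm box_residual
#> 1        334         2000         34       12    6.44     1    72.5      9.45e-7

loc_scores <- predict(m, extract_at(prep$localities[c("lon","lat")], base)[vars])
th <- derive_thresholds(loc_scores)
th
#> <threshold_set> n = 417 | optimal > 0.5117 | intermediate > 0.2415 | marginal >= 0.037

scen   <- default_scenarios()
stacks <- purrr::map(seq_len(nrow(scen)),
                     \(i) generate_future(base, scen[i, ])) |>
  rlang::set_names(paste0(scen$scenario_id, "_", scen$date))
proj <- project_scenarios(m, stacks)
tab  <- tabulate_localities(prep$localities, proj, th, spec)
summarise_classes(tab$table) |> filter(date == "2080")
#>   scenario_id date      n suitable unsuitable pct_unsuitable
#> 1 A1B         2080    417      162        255          61.2
#> 2 A2A         2080    417      228        189          45.3
#> 3 B2A         2080    417      314        103          24.7
```

By 2080 the harshest scenario leaves 61% of localities outside all
suitability thresholds, the mildest 25% — the same qualitative ordering
and decline pattern the method produces on the real species, with 0
unsuitable localities at baseline by construction of the thresholds.
`plot_locality_classes(tab$table)` draws the stacked-bar overview,
`plot_score_histograms(tab$trajectories, th)` the per-threshold
histograms, and `score_core(tab$trajectories)` ranks persistence
("core") localities. `run_pipeline(run_config(out_dir = "run1"))`
executes the whole chain and writes every artifact plus a checksummed
manifest.

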