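# urbantol

Urban tolerance indices for bird species from community-science
checklists and satellite night-time lights.

## What it does, and for whom

Ecologists increasingly rank species by how well they tolerate
urbanisation using two broad-coverage data sources: community-science
checklists (survey events reporting all species detected plus observer
effort) and satellite radiance from artificial light at night (ALAN, in
nW cm⁻² sr⁻¹), a continuous proxy for how built-up a location is.
`urbantol` packages that analysis as tested, reusable R components:

1. **Filter** checklists to complete lists under standard effort caps
   (stationary/travelling/area-search protocols, ≤ 300 min, ≤ 5 km,
   a configurable date window) and **clip** them to species ranges.
2. **Extract** each checklist's ALAN covariate: the median radiance of
   raster pixels within a 5-km buffer (monthly layers first composited
   by per-pixel median).
3. **Thin** the data to at most one checklist per 5-km hexagonal grid
   cell per week per year — detections and non-detections sampled
   independently, so class balance survives the thinning.
4. **Fit** a per-species negative-binomial log-link regression

   log μ = β₀ + β_ALAN·x + Σⱼ fⱼ(effortⱼ),  Var(y) = μ + μ²/θ,

   with fixed-df thin-plate spline smooths (k = 4) for observer number,
   joint location, duration, day of year and distance, and a cyclic
   cubic smooth (k = 5, period 1440 min) for start time.
5. **Average** β_ALAN over repeated subsample-and-fit runs (default
   100): the mean is the species' *urban tolerance index* (positive =
   tolerant, negative = avoidant), reported with the 2.5–97.5
   percentile interval of the run estimates. Species with fewer than
   1000 detection checklists are excluded.
6. **Regress** the indices on species traits (body mass, nest substrate
   breadth, habitat breadth, feeding guild, migratory status) by OLS
   with z-scored quantitative traits, drop-one F tests, and Student-t
   confidence intervals.

A synthetic-world generator (`synth_config()`, `make_alan_raster()`,
`simulate_checklists()`, `simulate_species_counts()`,
`simulate_trait_table()`) produces ALAN landscapes, brightness-biased
checklist effort, NB counts with known radiance slopes, and trait
tables with a known body-mass effect — so the entire chain is testable
by parameter recovery without downloading anything.

Rasters are read and written as plain-text ESRI ASCII grids
(`read_ascii_raster()`); range polygons come from GeoJSON
(`read_geojson_ranges()`); checklist tables use the familiar
tab-separated basic-dataset layout (`read_checklists()`).

## A worked example

```r
library(urbantol)

cfg       <- synth_config(n_checklists = 5000, seed = 7)
raster    <- make_alan_raster(cfg)
checklists <- simulate_checklists(cfg, raster)
truth     <- species_truth("demo_sp", beta_alan = 0.5, theta = 1.5)
dataset   <- simulate_species_counts(checklists, raster, truth)

est <- compute_tolerance_index(
  dataset, grid = hex_grid(5), n_runs = 25, master_seed = 1,
  min_detections = 500
)
est
#> Urban tolerance index for demo_sp: 0.4457 [0.4373, 0.4526]
#>   (percentile CI over 25/25 runs) -> tolerant
```

The generating radiance slope was +0.5; the resampled index lands at
+0.45 — correctly signed, slightly attenuated because the class-balanced
thinning flattens detection-rate differences between bright and dark
cells (see the vignette's limitations section) — and the interval spans
the spread of the 25 resampling runs, not full sampling uncertainty.

```r
traits <- simulate_trait_table(24, mass_effect = -0.7, noise_sd = 0.4, seed = 2)
fit_trait_model(traits$index, traits$traits)
#> Trait model for the urban tolerance index (n = 24, R^2 = 0.7852)
#>                              term estimate     se        t ci_low ci_high
#> 1                     (Intercept)  0.27556 0.1550  1.77818 -0.053   0.604
#> 2                       body_mass -0.68732 0.0967 -7.11114 -0.892  -0.482
#> ...
#> Drop-one F tests:
#>                predictor df      F        p
#> 1              body_mass  1 50.568 2.47e-06
#> ...
#> References: feeding guild = generalist, migratory status = local dispersal
```

The true mass slope of −0.7 is recovered at −0.687 with the remaining
traits (which carry no signal here) near zero and non-significant.
`run_pipeline()` chains every stage — filter, clip, extraction,
inclusion, index, ranking, trait model — from raw tables to an output
bundle with a reproducibility manifest, and `plot()` methods draw the
tolerance ladder and marginal-effect panels.

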