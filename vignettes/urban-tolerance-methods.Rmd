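---
title: "Scoring urban tolerance from checklists and night-time lights"
author: "urbantol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring urban tolerance from checklists and night-time lights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbantol)
```

## The problem

Community-science bird checklists record, for every survey event, which
species were detected, how many individuals, and how much effort the
observer spent (duration, distance travelled, party size, time of day).
Pairing these observations with a continuous satellite measure of
urbanisation — upward radiance from artificial light at night (ALAN), in
nW cm^-2 sr^-1 — lets one ask, species by species, whether reported
abundance rises or falls with how built-up the surroundings are. The
answer, summarised as a single per-species coefficient, is an *urban
tolerance index*: positive values mark urban-tolerant species, negative
values urban avoiders. A second regression then asks whether ecological
traits (body mass, nest substrate breadth, habitat breadth, feeding
guild, migratory status) explain the variation in tolerance across
species.

`urbantol` implements this chain as reusable, tested components:

1. **Filtering.** Only complete checklists (the observer reported
   everything detected, so absence is informative) under standard effort
   caps enter the analysis: stationary/travelling/area-search protocols,
   duration at most 300 min, distance at most 5 km, observation date
   inside a configurable window (default 2010-01-01 to 2021-06-30). The
   caps are inclusive — a 300-min checklist survives, a 301-min one does
   not — because the removal rule is "greater than" the cap. Checklists
   with missing duration or distance are removed under their own reason
   code; a missing distance on a stationary checklist is treated as 0,
   which is what the protocol implies.
2. **Range clipping.** Checklists outside a species' range polygon are
   dropped (vagrants, misidentifications). Boundary points count as
   inside: whether a record survives should not depend on floating-point
   luck at the polygon edge.
3. **Radiance covariate.** Each checklist gets the median radiance of
   all raster pixels whose centres fall within a 5-km buffer of its
   location. Monthly radiance layers are first collapsed to a single
   raster by the per-pixel median across months, which ignores missing
   pixels and is robust to transient lights (fires, flaring). Pixel
   membership is by centre-in-circle — an unambiguous rule that an
   exhaustive enumeration oracle can check exactly.
4. **Spatiotemporal subsampling.** Effort clusters where people live, so
   checklists are thinned to at most one per hexagonal grid cell (5 km
   across flats) per week per year — and, crucially, one *per detection
   class*: detections and non-detections are sampled independently.
   Without class balance the thinning would discard most detections,
   which are far rarer than non-detections.
5. **Abundance model.** Per species, counts are modelled with a
   negative-binomial log-link regression: a linear term in radiance
   (the quantity of interest) plus fixed-df spline smooths absorbing the
   effort covariates — thin-plate bases (dimension 4) for observer
   number, joint location, duration, day of year and distance, and a
   cyclic cubic basis (dimension 5, period 1440 min) for start time, so
   the fitted time-of-day effect wraps continuously across midnight.
6. **Resampled index.** Because step 4 is random, the subsample-and-fit
   cycle is repeated (default 100 runs) and the radiance coefficient is
   averaged; the 2.5th–97.5th percentiles of the run estimates accompany
   the mean. Species with fewer than 1000 detection checklists (counted
   after filtering, before subsampling; boundary inclusive) are excluded
   — below that the resampled coefficient is too unstable to rank.
7. **Trait regression.** The per-species indices are regressed on the
   five traits at once by ordinary least squares, quantitative traits
   z-scored, treatment coding with references *generalist* (feeding
   guild) and *local dispersal* (migratory status), a drop-one F test
   per predictor (multi-level factors dropped as a block), and Student-t
   confidence intervals on the residual degrees of freedom.

## The abundance model and its fitting

For species $s$ and checklist $i$ with count $y_i$,

$$y_i \sim \mathrm{NB}(\mu_i, \theta), \qquad
\log \mu_i = \beta_0 + \beta_{\mathrm{ALAN}} x_i
  + \textstyle\sum_j f_j(z_{ij}),$$

with $\mathrm{Var}(y_i) = \mu_i + \mu_i^2/\theta$ and each $f_j$ a
fixed-df regression spline. `fit_nb_glm()` alternates iteratively
reweighted least squares for the coefficients at fixed $\theta$ with a
one-dimensional maximisation of the profile log-likelihood over
$\log\theta$ (a safeguarded Newton step using analytic digamma/trigamma
derivatives). Convergence requires a relative deviance change below
1e-8 *and* a $\log\theta$ move below 1e-6, within 100 outer cycles; a
fit that exhausts them is returned flagged rather than thrown. Standard
errors come from the expected information $(X^\top W X)^{-1}$ with
$\theta$ held at its estimate — the usual NB-GLM convention, which
conditions on the dispersion. The tests pin this fitter against three
independent oracles: direct numerical maximisation of the joint
likelihood, the Poisson fit recovered at $\theta = 10^8$, and an
established independent NB-GLM implementation.

**Fixed df rather than penalised smoothing.** The effort smooths use
unpenalised regression-spline bases of fixed dimension (4, or 5 for the
cyclic term), not penalised splines with data-driven smoothing
parameters. With no smoothing-parameter selection rule specified for
the analysis, fixed-df bases make every fit a plain GLM: determinate,
fast inside a 100-run loop, and exactly checkable against likelihood
oracles. This is the one deliberate methodological simplification, and
the basis dimension is configurable per term via `smooth_spec()`.

**Basis construction.** The thin-plate basis is the low-rank
eigen-truncation of the full thin-plate construction on a capped knot
set (quantile knots in 1-D, an even deterministic subsample of unique
points in 2-D), with the polynomial null space appended and the
sum-to-zero constraint absorbed by a QR reparameterisation — so columns
sum to zero exactly and the basis plus an intercept reproduces affine
functions of the covariate to machine precision. The cyclic basis is a
periodic cubic B-spline design on evenly spaced knots with the same
constraint absorption; value and first two derivatives match at the
period seam. The location smooth is one joint 2-D thin-plate term
(latitude and longitude enter together), matching how location is
treated as a single nuisance dimension.

**Shared bases across runs.** `compute_tolerance_index()` builds the
smooth bases once on the full species dataset and subsets rows per run.
All runs therefore share identical basis functions and differ only
through the subsample — the quantity the resampling is meant to
isolate — and each run is also warm-started from one full-data fit, so
degenerate datasets in which every run draws the same rows produce
bit-identical estimates.

## Geometry choices

Hexagonal cells are a planar flat-topped lattice; *width* is the
across-flats diameter, which equals the centre-to-centre distance of
adjacent cells (5 km by default). Assignment maps a point to the
nearest lattice centre (hexagons are the Voronoi cells of their
centres) via cube rounding, which resolves boundary points
deterministically. A discrete-global-grid tessellation would be the
choice for a continental analysis; at 5-km cells the planar lattice on
a local projection is geometrically exact and testable against a
nearest-centre oracle, and the grid is configurable. Synthetic worlds
use planar kilometres directly; lon/lat inputs are projected with a
local equirectangular projection about the grid origin (kilometres true
along the reference parallel and meridian), and buffer distances on
WGS84 rasters use great-circle (haversine) distances.

## Seeds and reproducibility

One master seed fans out through `derive_seed()`, a platform-stable
integer hash of the seed plus arbitrary labels: the raster, the
checklist draw, and each (species, run) pair get independent,
reconstructible streams. Generator functions restore the caller's RNG
state, so package calls never perturb a user's session randomness. The
pipeline writes a manifest (config, seed, package version) that
suffices to re-run identically.

## What the synthetic world emulates — and what it does not

`synth_config()` describes a compact coastal-city landscape: 60 × 60 km
at 1-km pixels, three exponential light domes (peak 4 nW cm^-2 sr^-1,
decay length 8 km) over half-normal pixel noise (sd 0.1), and 20,000
checklists over a three-year window whose placement density follows
`(radiance + 0.05)^0.5` — brighter pixels attract more effort, the
signature bias of community-science data. Effort distributions are
typical of checklists (duration gamma with mean ~60 min, travelling
distance exponential capped under 5 km, party size 1 + Poisson(1),
morning-peaked start times). Counts follow the NB model above with the
radiance covariate computed *exactly as the pipeline later extracts it*
(buffer median at the checklist), so recovering `beta_alan` tests the
whole chain, not just the fitter. Peak radiance, extent and window were
chosen once so that the radiance covariate spans a few units (slopes of
±0.5 per unit are then biologically plausible detection-rate swings)
and so that grid-week strata are realistically crowded — a three-year
window over ~170 cells leaves the subsampler real thinning to do.

The generator deliberately omits: real geography and taxonomy, observer
random effects and identity, imperfect detection as a separate process
(effort effects on the mean can emulate either effort-dependent
detection or true abundance variation), spatial autocorrelation beyond
the shared radiance field, and group-checklist duplication. Passing
recovery tests on this world therefore demonstrates the pipeline's
internal consistency, not robustness to every bias in real data.

## Known limitations

**The index is attenuated, and its interval covers resampling noise
only.** Class-balanced thinning partially equalises detection rates
across strata by construction — a stratum with even one detection
always contributes it — which pulls the fitted radiance coefficient
toward zero. On synthetic worlds a generating slope of +0.5 is
recovered around +0.45, while −0.5 is recovered around −0.35 to −0.37:
the attenuation is asymmetric because checklist effort concentrates in
bright pixels, so an avoider's rare bright-area detections are the ones
most over-represented after thinning. (Fits on the full or
pooled-thinned data recover ±0.5 essentially unbiased; the per-class
balancing is the cause.) A second, smaller contribution is the
low-rank spatial smooth partially absorbing the spatially structured
radiance field. The sign — the quantity the classification rests on —
is essentially always correct in the recovery tests, and the ranking is
preserved, but the index's magnitude should be read as a
method-specific score, not an unbiased estimate of the generating
slope; at a slope of −0.5 the measured attenuation sits at the edge of
a ±0.15 recovery band. Consequently the percentile interval over the 100 runs
measures sensitivity to the random subsample, *not* full sampling
uncertainty: it is narrow, centred on the attenuated value, and should
never be read as a confidence interval for the generating slope.
`ci_type = "normal"` (mean ± 1.96 sd of runs) is available; percentile
is the default because it is distribution-free.

**Presence markers.** Checklists sometimes report a species with a
presence marker rather than a count. The default maps it to count 1 —
the minimal abundance consistent with a detection — with
`x_handling = "drop"` as the alternative. Checklists missing a start
time survive filtering but drop out of model fitting (the time-of-day
smooth needs the covariate); the fit reports how many rows it dropped.

**Week convention.** Weeks are 7-day blocks from 1 January, days
365/366 folded into week 52, and strata are per (cell, year, week) by
default; `week_scheme = "pooled"` collapses years, the other defensible
reading of "every week of the year across all available years".

## Problem sizes used by the tests

Unit tests run on small worlds (3000–4000 checklists) with reduced run
counts; the calibration suites use 500 replicate 24-species trait
tables, 1000-case geometry oracles, 10,000-seed uniformity checks, and
20 replicate 20,000-checklist worlds with 25 runs per species for
end-to-end recovery — sizes at which every Monte-Carlo bound in the
tests is stable under the fixed seeds. `scripts/acceptance.R` recomputes
the same quantities from scratch at those sizes for any seed.

## A worked miniature

```{r example, eval = FALSE}
cfg <- synth_config(n_checklists = 5000, seed = 7)
raster <- make_alan_raster(cfg)
checklists <- simulate_checklists(cfg, raster)
truth <- species_truth("demo_sp", beta_alan = 0.5, theta = 1.5)
dataset <- simulate_species_counts(checklists, raster, truth)

grid <- hex_grid(5)
est <- compute_tolerance_index(
  dataset, grid = grid, n_runs = 25, master_seed = 1, min_detections = 500
)
est

traits <- simulate_trait_table(24, mass_effect = -0.7, noise_sd = 0.4, seed = 2)
fit_trait_model(traits$index, traits$traits)
```
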