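---
title: "Class-specific habitat models and prey-mediated forecasting: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-specific habitat models and prey-mediated forecasting: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

predcast models intraspecific variation in the movements of a
wide-ranging coastal marine predator — a population stratified into
sex-by-maturity biological classes — and projects class-specific habitat
suitability a decade ahead by chaining predator models through predicted
prey redistribution. This vignette is the package's own account of the
methods: the models, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices made where the design was genuinely open.

## The modelling problem

Telemetry (acoustic and satellite) yields daily presence locations for
tagged animals, but no absences: occupancy models need a null
expectation of where each animal *could* have been. The package follows
the constrained correlated-random-walk (CRW) design: for every tracked
animal, simulated tracks are generated from the animal's own empirical
step-length and turning-angle distributions, started at its tagging
location, and constrained to the minimum convex polygon (MCP) of the
real track intersected with water. Real daily locations are labelled
presences (1), simulated locations pseudo-absences (0).

Animals are classified by sex and maturation length — females mature at
326 cm total length, males at 297 cm, with the threshold length itself
mapping to adult — and the study region splits at the 24.5°S coast
centroid into a tropical North (`lat > -24.5`) and a temperate South
(`lat <= -24.5`, boundary inclusive south).

## Environmental covariates

Daily gridded fields (SST, chlorophyll-a) are aggregated onto a regular
half-degree grid with half-open cells `[edge, edge + 0.5)`. For each
daily location, the 12 preceding days of the matched cell are split into
two 6-day halves, each averaged over its non-missing (cloud-free) days:

* `mean_recent` — mean of days −6..−1;
* `derivative` — mean(days −12..−7) − mean(days −6..−1);
* `sst_optimal` — `mean_recent` − 22 °C, the deviation from the
  species' proposed thermal optimum;
* `oni` — the monthly ENSO anomaly index of the location's calendar
  month, with strict ±0.5 °C event thresholds (index < −0.5 cold-phase,
  > 0.5 warm-phase, everything else neutral — the thresholds themselves
  are neutral).

Two open choices here were resolved as follows and are configurable:

* **Derivative sign.** "First half minus second half" is read with the
  *earlier* six days as the first half, so a positive SST derivative
  means cooling toward the location date. `half_order =
  "late_minus_early"` flips the convention; nothing downstream depends
  on the sign beyond interpretation.
* **Missing-data rule.** Each half requires at least one non-missing
  day; a location with an empty half is flagged unusable and excluded
  from fitting. This maximises usable rows while keeping both halves
  informed; no other gap-filling is attempted.

## The descriptive models

All four models are penalized additive models fitted by penalized IRLS
(`mgcv`), with smoothing parameters chosen by GCV — deterministic given
the data. "Random effects" are i.i.d.-Gaussian-penalized factor
intercepts (`bs = "re"`), the standard ridge equivalence, so a single
penalized-likelihood fit covers smooths and random intercepts together.
Interacting smooths (class × covariate, region × covariate) are capped
at basis dimension k = 10 against overfitting; month enters as a cyclic
spline.

* **Model 1 (latitudinal movement):** Gaussian, response = latitude of
  real daily locations; class-interacting smooths of `sst_optimal`,
  month, `derivative_sst`, `oni`, `derivative_chla`; random intercepts
  for animal, tagging region, year.
* **Models 2a/2b (occurrence):** binomial presence vs pseudo-absence,
  fitted separately in the North and South regions. The South model
  omits the tagging-region random intercept: animals tagged in the
  North are not observed in the South, so the term is confounded.
* **Model 3 (vertical movement):** Gamma (log link) daily maximum dive
  depth, pooled across classes, with region × `oni` and region × month
  smooths.

Classes observed on fewer than six animals are excluded with a warning
before class-interaction models are fitted. Tracks are first reduced to
one position per animal-day (daily median, then a 150 km/day speed
filter — a documented simple QC standing in for tag-specific location
processing) and thinned so consecutive retained locations are at least
0.25° apart (greedy scan against the last *retained* location, boundary
inclusive; the alternative reading — distance to the last *observed*
location — is noted but not used).

**Stepwise selection.** Candidate terms are added forward; a term is
retained when it lowers AIC by more than 2 (equivalently, its Akaike
weight within the current-vs-candidate pair exceeds ~0.73). The
threshold is configurable; 2 is the conventional "substantial support"
cut. Every comparison is recorded in a trace. A report-only Pearson
correlation screen (|r| ≥ 0.7 flags) is available for the candidate
set.

**Deviance decomposition.** The split of deviance explained into fixed
and random shares is defined by nested refit: the fixed share is the
deviance explained by the model refitted without its random intercepts
on the same rows; the random share is the full model's deviance
explained minus that, clamped at zero (independent GCV selection can
cross by numerical slack). This is one defensible construction; it is
exact for the saturated and the no-random cases and monotone for nested
fits.

## The forecast chain

1. Per-class gridded counts of daily locations over the observation
   period (half-open 0.5° cells).
2. A joint Poisson log-link GLM of counts on the `log(x + 1)` prey
   occurrence of all candidate prey species; species retained when
   positively associated and significant at p < 0.05 (per species, no
   multiplicity correction — the many-small-tests convention of this
   literature; the choice is isolated in one argument).
3. Per retained species, a Gamma (log link) thermal response model of
   `log(occurrence + 1)` on a smooth of climatological mean SST,
   restricted to occupied cells (Gamma needs positive responses; zeros
   carry no thermal information here). Species with fewer than 30
   occupied cells, a constant response, or a non-significant smooth
   (p ≥ 0.05) are excluded — no detectable thermal signal means the
   species cannot be projected forward.
4. Partial (temperature-only) vs full (temperature + prey) Poisson
   models of predator counts, compared by analysis of deviance: the
   deviance drop is referred to χ² with degrees of freedom equal to the
   number of added prey terms (each a 1-df linear coefficient). A
   species enters the full model only if it survived *both* screens in
   steps 2 and 3.
5. Projection: for each forecast month, each retained prey layer is
   predicted from its thermal model at the forecast SST; the
   (SST, predicted prey) covariates feed the full model to give
   per-cell predicted intensity. Monthly layers average into yearly
   layers, yearly layers into the decadal suitability map — the
   aggregation identities hold exactly and the projection is
   deterministic given the fits.

The climatological mean SST is computed daily → monthly → yearly →
overall, so unevenly cloudy months do not bias the long-term mean. Prey
projections are used as raw predicted values (no thresholding or
renormalisation before entering the full model). The
intensity-weighted latitudinal centroid of the decadal layer is the
package's diagnostic for poleward shift.

## The synthetic-data generators

The study's raw inputs (telemetry, remote sensing, biodiversity-portal
prey records) are not redistributable, so every stage is validated on
generators whose ground truth is known:

* **Fields** (`gen_env_series()`): value = base mean + latitudinal
  gradient + day-of-year sine + linear trend + Gaussian noise, with
  uniform random missingness. Defaults describe an east-Australian
  coastal strip: 40°S–8°S, ~152.5–162°E at 0.5°, 22.5 °C at the
  mid-latitude, 0.35 °C per degree latitude, 2 °C seasonal amplitude,
  0.3 °C noise, 5% cloud missingness. Leap days share day-of-year 365
  (phase is irrelevant to every test). The latitude reference is the
  bbox mid-latitude.
* **Index** (`gen_oni_series()`): monthly sinusoid + noise; defaults
  (amplitude 1.2 °C, 48-month period) cross the ±0.5 event thresholds
  in both directions.
* **Tracks** (`gen_tracks()`): a CRW (gamma step lengths with mean
  `step_scale`, wrapped-Gaussian turning with sd `π(1 − persistence)`)
  whose heading choice among candidate directions is weighted by
  `exp(−(SST − optimum)² / 2σ²)` at the candidate end point. Setting
  `thermal_sd = Inf` recovers the unbiased kernel exactly. Animals
  carry sex and total length drawn uniformly within their class's slice
  of the observed 150–386 cm range.
* **Prey** (`gen_prey_tables()`): Poisson counts around a Gaussian
  thermal niche, or a spatially uniform expectation for
  temperature-insensitive species.
* **Land** (`make_coast_mask()`): a straight coastal meridian (land to
  the west), so the geometry of constraint tests is analytic.

What the generators do **not** emulate: mesoscale eddies and real
bathymetry, tag-specific location error (ARGOS ellipses, acoustic
receiver geometry), temporally blocked movement modes, spatially
autocorrelated cloud cover, and observation effort gradients in the
prey records. Passing tests therefore demonstrate that the pipeline's
estimators recover known structure under clean assumptions — not that
real-data artefacts are handled; the QC and thinning steps exist for
those but are only exercised on simple constructed cases.

## Numerical choices and degenerate inputs

* Positions propagate on a local tangent plane (km → degrees with a
  `cos(lat)` longitude correction) — adequate at daily step scales
  (tens of km); distances and bearings use the haversine sphere.
* CRW rejection sampling redraws *both* step length and turning angle,
  up to 100 attempts per step, then holds the previous position; this
  keeps every simulated track the same length as its source track,
  which the presence/absence design requires. An animal whose first
  step is impossible in every simulation is a geometry error, not a
  silent hold. Whole-track rejection was considered and not used (it
  would bias step distributions near boundaries and is far more
  expensive).
* Only the first `n_keep = 45` of `n_sim = 100` simulations are used,
  in simulation-index order; `covariate_stabilisation()` exposes the
  running covariate means that justify the cut-off for any given
  dataset.
* Turning angles wrap to (−π, π]; exactly −π maps to π.
* A `by`-factor smooth whose factor has a single level in the data
  degrades to a plain smooth; single-level random intercepts are
  dropped with a message. Rank-deficient designs error, naming the
  offending term. Binomial responses must be 0/1 and Gamma responses
  strictly positive; model fits require 50 usable rows by default.
* All generators and the simulator take integer seeds and are exactly
  reproducible; seeded code never disturbs the caller's RNG state.

## Problem sizes used in the tests

The shipped test-suite and acceptance-script scenarios use sizes chosen
to make estimator behaviour unambiguous at desk scale: 1,000 random
covariate windows against a brute-force oracle; 100 simulations × 51
daily positions for the constraint check; 500 resampled steps/angles
for the kernel-fidelity KS tests; ~5,000 presence/pseudo-absence rows
for thermal-optimum recovery and the shuffled-label null (200
replicates of 2,000 rows for type-I calibration); 500-cell grids for
the prey chain, with the prey-dependent predator scenario using a 1.3
log-linear coefficient on realised prey occurrence so that the
partial-vs-full contrast reflects genuine prey-mediated signal; and a
120-month, +0.3 °C/yr warming forecast for the projection-direction
check.

## Known limitations

* MCP is the only home-range constraint (no kernel densities); steps
  resample i.i.d. from pooled empirical distributions, with no
  behavioural switching or temporal blocking.
* The fixed/random deviance split depends on the nested-refit
  definition above; other constructions give different numbers.
* Prey screening uses per-species p < 0.05 without multiplicity
  control; with many candidate species some false retentions are
  expected.
* Forecast skill is entirely conditional on the forecast SST fields
  supplied; no ensemble handling or downscaling is provided.
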