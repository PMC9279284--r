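---
title: "Methods: from 210Pb profiles to a global lake carbon-burial budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from 210Pb profiles to a global lake carbon-burial budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakeburial)
```

`lakeburial` implements the chain of computations that turns raw
unsupported-lead-210 sediment-core profiles into biome-stratified,
area-weighted estimates of recent (~50–100 yr) organic-carbon (OC) burial in
lakes, together with the regression and source-apportionment analyses that
typically accompany such a synthesis. This vignette documents the models,
their assumptions, the tunable parameters, the numerical choices, and what
the synthetic-data generators do and do not emulate.

## Geochronology: the CRS and CIC age models

Unsupported (excess) ²¹⁰Pb is the total ²¹⁰Pb activity minus the
²²⁶Ra-supported component, and decays with
$\lambda = \ln 2 / 22.3\ \mathrm{yr^{-1}}$ (`PB210_LAMBDA`). Two classical
age models are provided.

**CRS (constant rate of supply)** assumes a constant flux $P$
(Bq cm⁻² yr⁻¹) of excess ²¹⁰Pb to the sediment surface, whatever the mass
accumulation rate (MAR) does. If $I(m)$ is the excess inventory
(Bq cm⁻²) below cumulative dry mass $m$ (g cm⁻²) and $I_0$ the whole-core
inventory, then

$$t(m) = \frac{1}{\lambda}\ln\frac{I_0}{I(m)}, \qquad
  \mathrm{MAR}(m) = \frac{\lambda\, I(m)}{C(m)},$$

with $C(m)$ the excess concentration (Bq g⁻¹). CRS tolerates a changing
MAR and is the model used for the recent burial rates this package targets.

**CIC (constant initial concentration)** assumes the *concentration*
deposited at the surface is constant, so
$t(z) = \lambda^{-1}\ln\left[C(0)/C(z)\right]$. It serves as a secondary
cross-check: on an ideal constant-flux, constant-MAR core the two models
agree, and the test suite verifies agreement to within 2 % over the
0–100 yr range.

### Numerical choices

Measurements are slab averages over contiguous intervals (typically 2 cm),
which drives several discretization decisions:

* **Inventory integration** uses the rectangular rule per slab
  (excess × dry bulk density × thickness), matching slab sampling exactly.
* **Midpoint inventories** are the *geometric* mean of the slab-boundary
  inventories, which is exact when excess decays exponentially within a
  slab; with it, CRS ages on noiseless constant-flux cores are recovered to
  numerical precision and the MAR estimator's resolution error is
  second-order (< 1 % at 2 cm slabs for MAR ≥ 0.1 g cm⁻² yr⁻¹).
* **Tail inventory** below the deepest usable interval is the geometric sum
  of extrapolated slab contributions from a log-linear fit of excess
  against cumulative mass over the deepest three non-equilibrium intervals
  (`n_tail_fit`). The slab-sum form reproduces an exactly exponential
  profile with zero error, unlike a continuous-integral tail. The tail can
  be disabled (`tail = FALSE`), in which case profiles that have not
  reached equilibrium are rejected as incomplete.
* **Equilibrium clamping.** Raw excess at or below zero marks radiometric
  equilibrium. To keep logarithms finite such values are clamped to a floor
  of 0.1 % of the surface excess (`floor_frac`) and flagged; intervals
  below the deepest non-clamped interval carry no inventory and are
  reported as non-datable (the profile is truncated there with a warning).
* **CIC boundary referencing.** Because a slab average of an exponentially
  decaying concentration estimates the *top-boundary* age of the slab, CIC
  ages are assigned to slab tops and interpolated to midpoints; per-slab
  SARs are thickness/duration quotients. Profile inversions (excess
  increasing with depth) are monotonized by a running minimum from the
  surface, with a warning when the adjustment exceeds `inversion_tol`
  (default 5 %).
* **Dating window.** Ages beyond 150 yr (`max_age`) are reported but
  flagged `beyond_range`; ²¹⁰Pb carries little information there.

## Burial rates

Per-interval burial is
$\mathrm{OC\ burial} = \mathrm{SAR} \times \rho \times \mathrm{OC}/100
\times 10^4$ in g C m⁻² yr⁻¹ (the 10⁴ converts the cm-based product to a
per-m² figure). The *recent mean* burial of a core is the duration-weighted
average over intervals younger than the window (default 100 yr, the upper
end of the resolvable horizon; values in [50, 150] are accepted).

Whole-lake rates correct for sediment focusing by one of three methods:
the mean of two or more cores; a single depocenter core divided by a
sediment focusing factor (SFF) from the mean basin slope; or divided by
the SFF of the lake's maximum-depth class
(≤5, >5–10, >10–30, >30–90, >90 m). **The packaged SFF values
(1.0/1.5/2.0/2.5/3.0 by depth class; SFF = 1 + 0.056·slope%) are
assumptions**, morphometrically plausible but not derived from any bundled
dataset; they are deliberately exposed as an overridable YAML config
(`read_sff_table()`) and every result object records the SFF used.

## Classification and upscaling

Lakes are stratified into ten classes: seven natural terrestrial biomes,
or — when the surrounding land cover is cropland, urban or paddy field —
three human-altered classes split by annual air temperature at <7.5,
7.5–15.0 (closed interval) and >15 °C. The classifier is total and
deterministic; unknown cover labels are rejected with the accepted
vocabulary. Forest-cover covariates come from precomputed buffer pixel
counts (`forest_fraction()` excludes masked pixels from the denominator)
and satellite scenes are screened to within ±8 % (inclusive) of the
long-term river stage (`filter_by_water_level()`).

Class summaries are arithmetic means with SE = sd/√n on *untransformed*
rates (the log transform is reserved for hypothesis tests). Upscaling
multiplies class means by class lake areas, sums to a Tg C yr⁻¹ budget,
and back-converts to an area-weighted mean rate. Classes with area but no
data contribute zero flux and are flagged `no_data`; by default their area
is excluded from the weighted-mean denominator so the weighted mean refers
to the area the data represent.

Because per-class global lake areas are not bundled, the package ships a
**synthetic** class-area table (`synthetic_class_areas()`,
`inst/extdata/class_areas_synthetic.csv`). It is pinned to well-established
anchors — 2.67 × 10⁶ km² of natural lake area globally, ~65,200 km²
(~3 %) of it in humid tropical forest, a poleward-heavy distribution of
the remainder — and chosen once so the packaged defaults form an
internally consistent worked example. It is not a measured dataset and
should be replaced for any real analysis.

## Source apportionment

Surface-sediment signatures (thickness-weighted δ¹³C and molar C:N over
the top 6 cm) are classified against rectangular endmember regions for C₃
soil organic matter, C₃ woody plants, C₄ grasses and phytoplankton. A
point inside exactly one rectangle is assigned to it (edges count as
inside); points inside none, or inside two or more (ambiguous), are
unclassified, so contributions plus the unclassified share always sum to
100 %. The default rectangle boundaries are literature-informed
assumptions exposed via `endmember_set()`/`read_endmembers()`; no tie-break
between overlapping sources is attempted because none is defensible
without additional tracers.

## Regression and group statistics

* The temperature models are ordinary least squares on untransformed
  rates: linear for natural-biome lakes, second-order polynomial for
  forest OC accumulation.
* The forest-cover model $y = a e^{bx}$ is fitted by nonlinear least
  squares so the coefficient SEs refer to the original scale; the
  log-linear OLS fit provides the starting values (and coincides with the
  NLS solution on noiseless data). `nls` runs with `scaleOffset = 1` so
  exact-fit data converge; constant responses degenerate cleanly to
  $b = 0$, $a = \bar y$.
* Group comparisons run one-way ANOVA with Tukey's post-hoc test on
  natural-log rates (base unstated in most syntheses; natural log chosen
  here), summarised as a compact letter display at family-wise α = 0.05
  via `multcomp`. Kolmogorov–Smirnov, Bartlett and Kruskal–Wallis results
  are reported as diagnostics alongside, since field datasets routinely
  fail strict normality.
* Buffer selection maximizes r²; ties go to the smaller (more local)
  buffer.
* `variance_curve()` draws subsamples without replacement, so its
  expectation equals the full-sample variance at every subsample size; a
  flat curve is the expected behaviour, and flattening of the *spread* is
  what indicates sufficiency.

## What the synthetic generators emulate — and what they do not

`make_core()` implements the CRS premise exactly: the concentration
deposited at age $t$ is $P/\mathrm{MAR}(t)$, slab averages are computed in
closed form from boundary ages, and multiplicative lognormal (mean-one)
noise emulates counting error. `make_lake_dataset()` draws class burial
populations from lognormals moment-matched to each class's target mean and
population SD (SE·√n at the class's study size), with temperatures
truncated to the anthropic bins where needed so classification is
consistent by construction. `make_source_samples()` allocates samples to
sources by largest-remainder rounding and draws them uniformly inside the
rectangles, with unclassified mass placed outside all rectangles.
`make_forest_gradient()` offers multiplicative lognormal noise (the
realistic structure for positive skewed rates) or additive Gaussian noise
(the structure unweighted NLS assumes, used for CI-calibration checks).

These generators validate the *machinery*: unit handling, age-model
algebra, moment recovery, classification logic, estimator calibration.
They do not emulate core disturbance (mixing, hiatuses, compaction trends),
spatially correlated burial within biomes, non-lognormal outliers,
endmember points scattered outside their nominal rectangles, or errors in
the GIS-derived covariates. Passing tests therefore demonstrate
correctness of the computations under the stated models, not robustness of
the scientific conclusions to violations of those models.

A known calibration limitation: under multiplicative noise the unweighted
NLS standard errors of the exponential model are mildly optimistic for $b$
(the error variance grows with the mean), so Wald intervals undercover
slightly; calibration is verified under the model's own additive-error
assumption.

## Problem sizes and determinism

Every generator is a pure function of its scenario and seed. The test and
acceptance suites use sizes chosen to make Monte-Carlo error small relative
to the tolerances while remaining quick on a laptop: 30-interval cores,
5 accumulation rates and 5 noise seeds for dating recovery; 10⁴–2×10⁴
lakes per class for moment checks (3 Monte-Carlo SEs); 200 replicates for
CI coverage; 1000 null simulations for the ANOVA type-I rate (±1.5 %
band); 50 replicates for buffer-selection consistency.

## Worked example

```{r example, eval = FALSE}
library(lakeburial)

sim <- make_core(core_scenario(mar = 0.15, noise_cv = 0.05, seed = 1))
dated <- crs_date(sim$profile)
recent_mean_burial(dated, window = 100)

lakes <- make_lake_dataset(seed = 1)
lakes$class <- classify_lake(lakes$biome, lakes$land_cover, lakes$annual_temp)
budget <- upscale_global(summarize_classes(lakes), synthetic_class_areas())
budget
compare_to_emissions(budget$total_flux_tg, 320, 0.913)
```

The end-to-end composition, with per-stage CSV outputs and a JSON manifest
(seed, versions, md5 checksums), is `run_pipeline()`.
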