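---
title: "Thermal landscapes, performance curves and modifying capacity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal landscapes, performance curves and modifying capacity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoscape)
```

`thermoscape` evaluates how a change in vegetation — here, stands of
invasive trees in a native shrubland — alters the thermal habitat available
to a small ectotherm, from the animal's own performance data up to
habitat-level statistics. This vignette documents the models, the tunable
parameters and their defaults, the synthetic-data generator used for
validation, and the numerical and design choices a maintainer should know
about.

## 1. From righting trials to a performance curve

### Performance points

The behavioural assay is the righting response: an overturned tortoise
returning to a prone position. The trait of interest is the *successful
righting time* (seconds); its reciprocal is the righting speed (s⁻¹), a
rate that increases with performance. `performance_points()`:

* drops failed repetitions (no successful righting: a missing time), since
  a zero speed is not an observation of the rate;
* converts each successful repetition to a speed and averages **speeds**
  per individual × treatment — the mean of reciprocals, which differs from
  the reciprocal of the mean time and weights fast repetitions correctly
  for a rate;
* pairs each point with the mean measured body temperature of its
  repetitions (the temperature the animal actually experienced), falling
  back to the treatment temperature only when no body reading exists
  (`temp_source` records which).

### Candidate curves and fitting

Thermal performance curves are unimodal and, in general, asymmetric. The
registry (`tpc_models()`) ships five candidates, all with ≤ 4 free
parameters so that six treatment temperatures cannot be overfitted:

| name | form | parameters |
|---|---|---|
| `flinn` | `1 / (1 + a + bT + cT²)` | 3 |
| `flinn_exp` | `1 / (1 + exp(a + bT + cT²))` | 3 |
| `gaussian` | `Pmax exp(−½((T−Topt)/σ)²)` | 3 |
| `briere2` | `aT(T−Tmin)(Tmax−T)^(1/b)` | 4 |
| `weibull` | Weibull-shaped curve with mode at `Topt` | 4 |

Two Flinn-type forms are deliberately included. The quadratic-denominator
form is exactly symmetric about its vertex; the logistic-exponent form
(the classical Flinn parameterisation) is asymmetric. Published
coefficient sets for this curve family are sometimes typeset without the
exponential, so shipping both lets a user reproduce either reading of a
printed equation; the synthetic trial generator uses the
quadratic-denominator form with `a = 76.79`, `b = −4.45`, `c = 0.07`
(vertex ≈ 31.8 °C, peak ≈ 0.14 s⁻¹) because that is a fully specified,
closed-form truth against which recovery can be tested analytically.

`fit_tpc()` minimises the residual sum of squares with the
Levenberg–Marquardt algorithm under box constraints (via `minpack.lm`),
from a **seeded multi-start grid** (default 20 starts): the quadratic and
exponent families have genuine local minima, and the starts are built
around the empirical maximum (vertex position/height sampling for the
Flinn forms) so that at least some starts begin in the right basin. The
best converged start wins; a fit with no converged start is flagged rather
than silently reported.

### Model selection and traits

Selection uses the small-sample corrected AIC in its least-squares form,

$$\mathrm{AICc} = n\,\log(\mathrm{RSS}/n) + 2k + \frac{2k(k+1)}{n-k-1},$$

with `k` counting the curve parameters **plus one** for the residual
variance. That convention matters when comparing across software, so it is
fixed and documented (`aicc()`); a test cross-checks it against the
explicit Gaussian log-likelihood formula. Ties go to the model with fewer
parameters, then alphabetically.

`tpc_traits()` extracts `Topt` by bounded scalar maximisation over the
observed temperature support widened by a `margin` (default 5 °C), `Pmax`
as the curve value there, and the suitability band (default fraction 0.8,
the *B80*) by root-finding `curve(T) − 0.8 · Pmax` on each side of `Topt`
(tolerance 1e-9). If the curve never drops to the threshold inside the
search interval, that bound is reported as `NA` — *not estimable from the
tested temperature range* — rather than extrapolated; with trial
temperatures only up to 35 °C this is the honest outcome for the upper
limit under several of the candidate forms. A gridded unimodality check
(2001 points) rejects pathological fits by name before any trait is
reported.

### Pooling

Whether a single curve may be fitted to all animals is decided by
`righting_screen()`: mean speed is modelled against a quadratic polynomial
in body temperature plus candidate grouping terms (site, season, sex) with
a random intercept per individual; fixed structures are compared by ML
AIC with the random structure held fixed. If no grouping term survives,
the verdict is `pool` — one curve for the species — otherwise `split`
with the surviving terms listed.

## 2. Cleaning the logger record

Cleaning never edits a temperature; it only removes rows, and the counts
reconcile exactly (`raw = retained + Σ removals`, asserted at run time).
The steps run in a fixed order:

1. **Service windows** — all samples of a logger within ±1 h (closed
   interval) of a deployment or reprogramming event are dropped; handling
   the logger perturbs it. Overlapping windows are unioned.
2. **Outliers** — samples outside plausibility bounds (default
   [−10, 70] °C) and *isolated spikes* whose absolute jump from **both**
   temporal neighbours exceeds `spike_delta` (default 20 °C). This is an
   explicit, reproducible surrogate for the manual visual screening such
   datasets usually receive; the parameters are exposed so a user can match
   a particular manual pass.
3. **Daytime and study window** — hours 07:00–19:00, both boundaries
   inclusive (13 samples per full day). Inclusivity at both ends is a
   declared choice: it maximises data and makes the per-day sample count
   unambiguous.

Timestamps are naive local clock time throughout (loggers run on a fixed
local setting; no DST arithmetic). Seasons are austral and month-based:
June–August winter, September–November spring, December–February summer
(December and the following January belong to the same season), March–May
autumn.

## 3. Landscape metrics

All metrics are keyed by site × habitat × quadrat (× date × hour where
relevant) and returned as tidy rows; missing logger-hours simply reduce
the number of contributing models for that hour — no imputation.

* **Daily composition** (`daily_composition()`): median, min, max and
  range per quadrat-day, pooling all of the quadrat's loggers of one
  stratum. Pooling (rather than averaging per-logger ranges) is the
  declared reading of "daily range": it is the range an animal moving
  freely within the quadrat could encounter that day.
* **Hourly spatial range** (`hourly_spatial_range()`): max − min across
  the quadrat's ground models at each hour; needs ≥ 2 models reporting.
* **de index** (`de_index()`, `hourly_de()`): the mean absolute deviation
  of microsite temperatures from the suitability band — 0 inside the
  band, distance to the nearer violated bound outside. Zero if and only
  if every microsite is within the band.
* **Exposure times** (`minutes_any_within()`, `minutes_half_beyond()`):
  each hourly sample stands for its whole hour (× 60 min), since loggers
  record instantaneous hourly values and no sub-hourly information exists.
  "At least half" uses the ceiling rule for odd counts (2 of 3) — the
  stricter reading, declared because it is otherwise ambiguous.
* **Band occupancy** (`band_occupancy()`): each model classified into
  exactly one of within/above/below; percentages sum to 100 per
  quadrat-hour. The daily-course aggregation offers both pooling of all
  model-hours (default) and averaging of per-quadrat-hour percentages,
  because the two differ when model counts vary.
* **Peak heat hour** (`peak_heat_hour()`): the daytime hour with the
  highest seasonal median temperature, ties resolved to the earliest hour.

## 4. Modifying capacity

For each site × habitat × quadrat × season and stratum (ground and
underground separately), `fit_air_coupling()` fits

$$T_{\text{microsite}}(t) = \alpha + \beta\,T_{\text{air}}(t) + u_{day(t)} + \varepsilon(t)$$

with a random intercept per day (hourly series are strongly autocorrelated
within days; the day intercept absorbs synoptic-scale weather so that β
reflects the diurnal coupling). A slope β < 1 buffers air temperature,
β > 1 amplifies it. When fewer than two days are present or the
random-effect fit is singular the model falls back to OLS, flagged in the
output; the two agree exactly when day-level variance is zero.

`modifying_areas()` integrates the deviation of the fitted line from the
unity line, `d(x) = α + (β−1)x`, **analytically** over the observed air
range of that series: the positive part is the amplifying area, the
negative part the buffering area (≤ 0), their sum the total modifying
capacity (°C²). The integral is split exactly at the unity crossing
`x* = α/(1−β)` when it is interior; a crossing at a boundary is a
measure-zero point and contributes to neither side. Integrating over the
*observed* per-series air range (rather than a fixed global range) keeps
the areas data-supported with no extrapolation — the declared choice where
the convention is otherwise open; a per-day variant would simply sum the
same construction over days. Tests verify the analytic areas against
exact trapezoid integration with the crossing as a grid node, to 1e-9.

## 5. Habitat × season inference

`habitat_contrasts()` fits metric values against habitat and season with
site and quadrat as random intercepts (quadrat ids are constructed nested
within site × habitat, matching the sampling design, so `(1|quadrat_id)`
is automatically the nested term). The two-stage protocol is available:
random structures compared by **REML** AIC with the full fixed structure;
fixed structures (`1`, `season`, `habitat`, `habitat + season`,
`habitat * season`) compared by **ML** AIC with the chosen random
structure; winner refitted by REML. A strictly lower AIC wins — no ΔAIC
margin — with ties resolved toward the simpler candidate. Contrasts
(invaded − native, per season) come from `emmeans` on the final REML fit
with Satterthwaite degrees of freedom; when selection drops the habitat
term the contrast is still reported from a refit retaining it, flagged
`term_selected = FALSE`, so the estimate and its uncertainty remain
available for effect-size reporting. No multiplicity correction is applied
across the metric family (α = 0.05 per contrast); the intervals are 95 %
confidence intervals.

Null calibration: on 500 simulated null datasets (no habitat effect, site
SD 1 °C, quadrat SD 0.5 °C, residual SD 1 °C; 4 sites × 2 habitats ×
3 quadrats × 10 days, one season — small on purpose so the whole
calibration runs in well under a minute) the 95 % CI covers zero in ≈ 94–95 %
of replicates, which the test suite asserts at 95 ± 3 points.

## 6. The synthetic-data generator

The generator is first-class, tested code, not a fixture. It emulates:

* **Air forcing**: per season, a nighttime baseline plus a half-sine wave
  over 07:00–21:00 peaking at **14:00** — the observed timing of peak heat
  in this system — scaled by a seasonal amplitude. Defaults (baseline
  10/15/22/15 °C and amplitude 6/10/13/10 °C for winter/spring/summer/
  autumn) reproduce Western Cape daytime medians of roughly 14–16 °C in
  winter and 33–35 °C in summer. The half-sine is a deliberate
  simplification: it matches the diurnal shape without modelling radiation
  physics.
* **Ground microsites**: linear coupling to air,
  `T = α + β·T_air + ε`, with (β, α) per sun-exposure class — defaults
  full sun (1.5, −6), partial (1.2, −2), shade (0.9, 0.5), inside
  vegetation (0.75, 2) — plus a small per-logger jitter. Sun-exposed
  classes amplify (β > 1), shaded classes buffer (β < 1). Habitat
  availability mixes default to sun-heavy for native shrubland and
  shade-heavy under invasive trees. Classes are drawn per logger from the
  habitat mix, but a quadrat is never left all-one-class when alternatives
  exist: field protocols place the 3–4 models of a quadrat across
  *different* exposures on purpose, and an all-same-class quadrat would
  erase exactly the spatial-heterogeneity signal the design samples. Every
  planted (β, α) is emitted in a truth table for recovery tests.
* **Underground series**: running daily mean of air plus a damped
  (default 0.3), lagged (default 2 h) diurnal anomaly — smooth by
  construction, as buried sensors are.
* **Noise**: stationary AR(1) (default marginal SD 1 °C, lag-1
  correlation 0.6) on every series. `noise_sigma` is the *marginal* SD so
  its meaning does not change with `noise_phi`; hourly temperatures are
  strongly autocorrelated and iid noise would understate mixed-model
  standard errors. No published noise spectrum exists for this logger
  system, so these are stated placeholders, not field estimates.
* **Righting trials**: body temperature = treatment + equilibration noise
  (SD 0.7 °C); speed = generating curve at the body temperature + truncated
  Gaussian observation noise; failures are emitted with *no* time, with a
  probability concentrated at the cold extreme (and mildly at the hot
  extreme), mirroring how real failed attempts appear in such data.

Everything is deterministic given the config and seed, down to byte-stable
CSV fixtures.

**What the generator does not emulate** — radiative and conductive
microclimate physics, wind, soil moisture, topography, logger drift,
data gaps from device loss, and behavioural records. Passing tests on
synthetic data therefore demonstrate that the *computations* are correct
and that planted signals of realistic size are recovered; they do not
validate the linear-coupling model itself against field microclimates.

## 7. Problem sizes and determinism

The default scenario matches a study-scale deployment (4 sites ×
2 habitats × 5 quadrats × 3 ground models, buried sensors in 3 quadrats
per habitat, one air logger per site, hourly for a year). The test suite
and the acceptance script run scaled-down versions — week-long windows for
unit tests, a year at 2–4 sites × 3 quadrats for the ordering and
headline-quantity checks — sizes chosen so the full validation cycle runs
in a few minutes while leaving every seasonal contrast identifiable. All
randomness flows from explicit integer seeds; identical config + seed
reproduces identical tables.

## 8. Known limitations

* The linear microsite–air coupling is a statistical emulation; real
  microsites saturate at high radiation loads and decouple under wind.
* The B80 band treats performance as the only currency of suitability;
  hydric costs and behavioural constraints are out of scope.
* Hourly sampling bounds the time-resolution of the exposure metrics to
  whole hours (× 60 min).
* The upper bound of the suitability band is frequently not estimable
  when trials stop near the optimum — reported as `NA` by design, never
  extrapolated.
* Capacity areas are in °C² and comparable across cells only over similar
  air ranges; the summaries therefore group by season and stratum.
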