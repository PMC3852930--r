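---
title: "Methods: gridded population exposure and the health burden of PM10"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gridded population exposure and the health burden of PM10}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airhia)
```

## The problem

Time-series studies of air pollution and morbidity usually treat a city as
a single point: one monitor (or a network average) is taken to represent
everyone's exposure. When population density and pollution are both
spatially structured — as in a valley city whose residents crowd into a
narrow belt along the polluted corridor — the point assumption biases the
exposure estimate downward. `airhia` implements the gridded alternative:
interpolate the monitoring network onto a fine geographic grid, put the
population on the same grid, and weight exposure by where people actually
live, before propagating the result through an exposure-response function
into attributable cases and treatment costs.

The package is organised as a five-stage chain, each stage usable on its
own:

1. **Exposure surface.** Station TSP is converted to PM10 with a fixed
   factor (0.55), annual station means are interpolated onto a 0.01-degree
   grid by ordinary kriging, and gridded population is disaggregated to
   the same cells by mass-preserving areal weighting.
2. **Population-weighted exposure.** The overlay gives one row per
   populated cell with valid concentration; the population-weighted
   exposure level is `PWEL = sum(P_i C_i) / sum(P_i)`.
3. **Exposure-response.** Daily admission counts `Y_k` follow a Poisson
   log-link additive model
   `log E[Y_k] = alpha + DOW + beta * PM10(lag) + s(time, df) + s(Z_k, df)`
   with natural cubic spline smooths; the lag and the spline df are chosen
   by exhaustive AIC minimisation.
4. **Health impact.** With baseline rate `E0` at a threshold `C0`, the
   rate at concentration `C` is `E = E0 exp(beta (C - C0))` and the excess
   cases among `P` persons are
   `N = P E (1 - exp(-beta (C - C0))) = P E0 (exp(beta (C - C0)) - 1)`;
   the second form serves as the internal oracle in tests.
5. **Valuation.** Cost of illness is cases times a per-case treatment
   cost; the burden is also expressed as a percentage of regional GDP.

## Units

Published exposure-response coefficients in this literature are sometimes
printed per mg/m^3 (e.g. beta = 0.197 with an RR per 10 ug/m^3 of about
1.002 — the two are only consistent if the coefficient is per mg/m^3).
Internally everything is ug/m^3: a printed 0.197 per mg/m^3 is stored as
1.97e-4 per ug/m^3, and all reports show both conventions. Concentration
files may be declared as mg at the read boundary (`read_tsp_csv(unit =
"mg")`), which removes the classic 1000-fold foot-gun.

## The synthetic scene

Raw inputs for this kind of analysis — station series, census rasters,
hospital admission lists — are rarely available publicly, so the package
carries a first-class generator whose defaults define the study
conditions used throughout the tests:

| parameter | default | meaning and rationale |
|---|---|---|
| `domain_bounds` | 0.45 x 0.15 degrees | a narrow valley-city rectangle (~45 x 17 km) |
| `resolution` | 0.01 degrees | ~1 km cells, the classic exposure-grid scale |
| `n_stations` | 7 | a small urban monitoring network |
| `annual_mean_pm10` | 330 ug/m^3 | severe-pollution regime; the TSP baseline is calibrated so the true surface averages to this |
| `seasonal_amplitudes` | spring 0.45, winter 0.40 | Gaussian bumps at mid-April and mid-December; `summer_dip` 0.30 centred mid-August |
| `regional_sd` / `noise_sd` | 0.28 / 0.12 | shared synoptic log-normal shock plus station noise; gives inter-station correlation ~0.85-0.9 |
| `ridge_amp` | 0.20 | concentration enhancement on the urban belt, the gradient kriging must recover |
| `total_population` | 1.2 million | belt-shaped (anisotropic Gaussian ridge, two density centres), peak densities above 3700 per km^2 |
| `beta_true` | 2e-4 per ug/m^3 | RR ~1.002 per 10 ug/m^3, the weak-toxicity regime of crustal dust |
| `lag_true` | 4 days | single-day lag in the data-generating process |
| `baseline_rate` | 30 admissions/day | a plausible multi-hospital respiratory caseload for a city this size; baseline rates are seldom reported alongside published coefficients, so this is a free parameter |

Admissions are drawn from a Poisson law whose log-mean adds day-of-week
offsets, the lagged exposure effect, a slow quadratic time trend and a
smooth function of maximum temperature. The weather effect is deliberately
mild and smooth so that the estimation model's spline basis can represent
it: the generator is meant to test *recovery under the model's own
assumptions*, not robustness to gross misspecification.

Two generator choices deserve emphasis:

* **Shared synoptic shock.** A smooth seasonal cycle alone cannot produce
  the high day-to-day inter-station correlation real networks show;
  `regional_sd` adds a day-level log-normal shock common to all stations.
  With `noise_sd = 0` every station is an exact scaled copy of the
  regional signal (correlation 1), which the tests use as a limiting case.
* **Exposure in the DGP is the station-mean series,** not the kriged
  surface, so the recovery target for the regression stage is
  well-defined independently of the interpolation stage.

What the generator does **not** emulate: sandstorm episodes and other
synoptic extremes (its shocks are i.i.d. log-normal), anisotropic spatial
correlation, instrument error and missingness, population growth over the
fitting years, and any real census geography. Passing tests therefore
demonstrate internal correctness and recoverability under the stated
model, not performance on real monitoring data.

## Numerical choices

* **Variogram.** The family is a free choice (spherical default,
  exponential and gaussian available); parameters are fitted to the
  binned empirical semivariogram by Cressie-weighted least squares with
  the nugget fixed at zero, so ordinary kriging interpolates the stations
  exactly — the station-exactness test is then meaningful. Distances are
  planar degrees, adequate for sub-degree domains. An all-constant input
  degenerates to a tiny-sill model with a warning; duplicate station
  coordinates are rejected as a singular system.
* **Kriging.** One bordered system is factorised and solved against all
  cell centres at once; weights sum to one by construction (asserted to
  1e-8 in tests). Annual means are kriged once — daily surfaces would
  multiply cost ~365-fold with no effect on the annual-scale results.
* **Grid conventions.** Cells are addressed 0-based with row 0 at the
  north edge, matching the ESRI ASCII format used for I/O; values are
  evaluated at cell centres.
* **Population disaggregation** is areal-weighted and mass-preserving;
  conservation is asserted at 0.1% whenever the target covers the source.
  Populated cells with NODATA concentration are dropped and counted.
* **Regression.** The Poisson fit is plain IRLS (`stats::glm`); smooths
  are unpenalised natural cubic splines with knots at quantiles, so
  effective df equals basis dimension and AIC uses the exact parameter
  count. A `df = 1` smooth degenerates to a linear term. Rows lost to
  lagging are dropped, not imputed. Overdispersion is not modelled; the
  Pearson dispersion is reported as a diagnostic. AIC ties break toward
  fewer total df, then the smaller lag.
* **Impacts.** Negative excess (cells below the threshold) clamps to
  zero — a threshold model cannot be protective — and the clamp count is
  reported. Annualisation multiplies the daily burden by 365 (366 on
  request). Case confidence bounds propagate only the coefficient's
  uncertainty; baseline rate and population are treated as fixed, since
  no uncertainty is available for them.
* **Valuation rounding** is fixed (cases 1 decimal, costs integer, GDP
  percentage 3 decimals) so the table is bit-stable. Note that published
  tables of this kind occasionally carry internal rounding slips (e.g. a
  total of 5,995,440 printed where the row's own cases times unit cost
  give 5,995,374); the package always reports its own consistent product.

## Design decisions on the excess-risk equations

The concentration-response and visitor-count equations circulate in
garbled typeset forms in parts of this literature. The package adopts the
standard log-linear excess-risk reading — `E = E0 exp(beta dC)`, `N = P E
(1 - exp(-beta dC))` — which is the only reading consistent with the
Poisson relative-risk framework and which satisfies the internal identity
`N = P E0 (exp(beta dC) - 1)` used as an oracle. Likewise the visitor
decomposition is implemented as `ft = fp / (1 + dC beta)` with excess
`fp - ft = fp dC beta / (1 + dC beta)`, the only mutually consistent
arrangement of the published forms.

## Problem sizes used in validation

The recovery studies fit 5-year daily series (≈1822 usable days) at the
default scene; coefficient recovery uses 50 independent replicates and
the lag-selection study 25 replicates at a doubled effect size, which
gives the AIC search a clear signal while remaining inside a desk-scale
run. The closed-form identity checks use 1000 random parameter draws.
These sizes are the package's validation design and are reproduced
verbatim by the test suite.

## Known limitations

* Kriging from a seven-station network cannot resolve a concentration
  ridge much narrower than the station spacing: on the default scene the
  true surface's population-weighted uplift (~8%) is attenuated to ~2% in
  the kriged estimate. The package asserts the direction and a generous
  band for the uplift rather than a point value, because the magnitude is
  scene- and network-dependent.
* Absolute case counts require the exposed population and baseline rate;
  where a published table omits them, only its arithmetic (cases to costs
  to GDP share) can be reproduced, and the synthetic scene substitutes
  its own `P` and `E0`.
* Single-day lags only; distributed-lag structures, multi-pollutant
  models and penalised smoothness selection are out of scope.
* Plain geographic degrees throughout; no projections, no co-kriging.
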