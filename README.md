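# airhia

Gridded population-exposure assessment and health-impact valuation for
particulate air pollution (PM10), for epidemiologists and environmental
economists working from sparse urban monitoring networks.

City-scale time-series studies commonly assume everyone shares one
monitor's exposure. Where population and pollution are both concentrated —
e.g. a valley city whose residents live in a narrow belt along the
polluted corridor — that assumption understates exposure. `airhia`
implements the gridded alternative end to end:

* **TSP → PM10** by a fixed conversion factor (`PM10 = 0.55 × TSP`);
* **ordinary kriging** of station annual means onto a 0.01° × 0.01° grid,
  with a WLS-fitted spherical variogram (zero nugget, so the surface
  honours the stations exactly);
* **mass-preserving areal disaggregation** of a gridded population to the
  same cells, overlay, and the population-weighted exposure level
  `PWEL = Σ PᵢCᵢ / Σ Pᵢ`;
* **Poisson log-link additive regression** of daily hospital admissions,
  `log E[Yₖ] = α + DOW + β·PM10(lag) + s(time, df) + s(Zₖ, df)`,
  with natural-spline smooths and exhaustive AIC selection of the
  single-day lag (0–7) and smooth df; β is reported per μg/m³ and per
  mg/m³, with the Wald 95% CI (β ± 1.96·SE) and the RR per 10 μg/m³;
* **threshold-scenario excess morbidity**, `N = P·E·(1 − e^{−βΔC})`
  with `E = E₀·e^{βΔC}`, evaluated per grid cell for thresholds C₀ of 0
  (no safe level), 20 (WHO guideline) and 50 μg/m³ (national first-class
  standard), with case bounds propagated from the CI of β;
* **cost-of-illness valuation**: cases × per-case cost, and the share of
  regional GDP.

Raw station, census and admissions data for this kind of study are rarely
deposited publicly, so the package ships a first-class synthetic-scene
generator (`sim_config()`,
`generate_scene()`) with a retrievable truth record, used by the test
suite for parameter-recovery and burden-recovery studies.

## Worked example

The repository is organised as a numbered analysis under `analysis/`;
each stage is a thin driver over package functions and writes its tables
under `results/`:

```sh
Rscript analysis/01_simulate.R          # synthetic scene + truth record
Rscript analysis/02_exposure_surface.R  # kriging, overlay, PWEL
Rscript analysis/03_exposure_response.R # Poisson GAM, AIC lag search
Rscript analysis/04_health_impact.R     # threshold scenarios
Rscript analysis/05_economics.R         # cost of illness, %GDP
```

Stage 2 prints (seed 1):

```
grid mean PM10 : 343.0 ug/m3 (0.343 mg/m3)
PWEL           : 349.3 ug/m3 (0.349 mg/m3)
weighting effect: +1.8% -- people cluster where air is worse
```

i.e. weighting exposure by where people live raises the estimate above
the plain grid mean, the central point of the gridded approach. Stage 3:

```
Poisson exposure-response fit (n = 1818, lag = 4 d)
  beta  = 0.0002237 per ug/m3 (0.2237 per mg/m3)
  SE    = 3.862e-05; 95% CI (0.000148, 0.0002994) per ug/m3
  RR per 10 ug/m3 = 1.0022
  AIC = 11285.96; dispersion = 0.982
```

The AIC search recovers the generator's lag (4 days) and its coefficient
(true value 2e-4 per μg/m³) within one standard error. Stages 4–5 turn
the fitted function into the scenario table:

```
 scenario                      c0_ugm3 cases  total_cost gdp_percent
 zero                                0 884.9      584034       0.019
 WHO                                20 832.3      549318       0.018
 National first-class standard      50 753.9      497574       0.016
```

Excess cases and costs fall as the threshold rises; the burden is largest
under the no-safe-level assumption.

The same chain is available as a single call:

```r
library(airhia)
m <- run_pipeline(pipeline_config(), "results/run")
report(m)
```

## Package layout

* `R/` — the implementation: synthetic scene (`synthetic_data.R`),
  variography and kriging (`variogram.R`, `kriging.R`), exposure surface
  and overlay (`exposure.R`, `grid.R`, `io.R`), Poisson regression and
  model selection (`exposure_response.R`), impacts (`health_impact.R`),
  valuation (`economics.R`), orchestration (`pipeline.R`).
* `analysis/` — the numbered workflow drivers shown above.
* `tests/testthat/` — unit, property and end-to-end recovery tests.
* `vignettes/methods.Rmd` — the model, its assumptions, parameter
  defaults, numerical conventions and known limitations.
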