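# budorcas

Camera-trap population, activity and habitat analysis for takin
(*Budorcas taxicolor*) subspecies in Eastern Himalayan mountain systems.

Takin are large unmarked bovids: individuals cannot be distinguished on
camera-trap images, so density must come from encounter rates rather than
capture–recapture. This package implements the full monitoring chain used
for the Mishmi (*B. t. taxicolor*) and Bhutan (*B. t. whitei*) subspecies —
for ecologists running or re-analysing unmarked-ungulate camera-trap
surveys:

* **Independence filtering** — collapse triggered photo bursts into
  independent events per station × species (configurable window, default
  30 min), with survey-effort accounting and composition statistics.
* **Random encounter model (REM)** — with a sector detection zone of radius
  *r* and angle *θ* ≤ π, the mean profile width is *w̄ = r(2+θ)/π*, so
  density follows from the encounter rate *y/t* (events per camera-day) as

  *D̂ = (y/t) · π / (v · r · (2+θ))*

  for day-range *v*; per-speed estimates are averaged and extrapolated to a
  population over the suitable-habitat area.
* **Ideal-gas simulator** — a compiled movement simulation (animals on a
  torus, exact segment–sector detection) that validates the estimator
  end-to-end against known truth.
* **Activity rhythms** — von Mises kernel density on the 24-h circle,
  overlap coefficient Δ = ∫ min(f_A, f_B), circular peak detection, and
  month × elevation-zone migration profiles (rainy-season May–October shift
  above 3500 m).
* **Habitat suitability** — a minimal penalized maximum-entropy model over
  1-km² grids with the published class thresholds (potential 0.5–0.7, high
  0.7–1.0), habitat areas and range-overlap ratios; ESRI ASCII grid I/O.
* **Fixtures and generators** — the published survey-effort and density
  tables are packaged verbatim; synthetic survey, gas-model and
  Gibbs-landscape generators give every stage an input with known truth.

## Worked example

Reproducing the published density chain from the packaged tables:

```r
library(budorcas)
report_from_fixtures()
#>        species  ips camera_days  mcv     d1     d2 mean_density se_density
#> 1 B. taxicolor 1685        1238 1.36 0.1738 0.1720       0.1729     0.0134
#> 2    B. whitei 3152        1594 1.98 0.1429 0.1289       0.1359     0.0264
#>   area_km2 population se_population
#> 1    17314       2994           232
#> 2    25006       3398           660
```

Each row recomputes the encounter rate (1685 events over 1238 camera-days
gives 1.36 events/camera-day), averages the stored per-speed densities
(0.1729 and 0.1359 takin/km²), and extrapolates over the distribution area
(0.1359 × 25,006 km² → 3398 ± 660 animals; the Mishmi product 2993.6 rounds
to 2994, 0.05 % from the published 2995).

Validating the estimator against simulated truth:

```r
cfg <- gas_config(true_density = 0.2, speed = 5, radius = 0.01,
                  angle = 0.872, n_detectors = 100, duration_days = 10000,
                  seed = 42)
sim <- simulate_gas_model(cfg)
rem_from_simulation(sim)
#> [1] 0.2015345        # true density 0.2 /km^2
```

And a full synthetic survey through the pipeline:

```r
sv  <- generate_detection_table(survey_config(seed = 99))
out <- run_pipeline(sv$detections, sv$deployments, run_config(seed = 99))
out$log
#> [1] "read: 4170 detection records, 50 deployments"
#> [2] "filter: 4170 records -> 1390 independent events (0 excluded)"
#> [3] "summarize: 4 survey areas"
#> [4] "density: bhutan 0.7993/km^2, mishmi 0.4504/km^2"
#> [5] "activity: 2 rhythms fitted"
```

The `analysis/` directory runs the same chain as a narrative workflow
(`01_simulate.R` … `05_habitat.R`), writing tables under `results/`.

## Package layout

* `R/` — survey data model and filtering, REM, activity, habitat/maxent,
  synthetic generators, fixtures, pipeline.
* `src/` — the compiled gas-model movement core.
* `inst/extdata/` — the packaged survey-effort and density tables (CSV).
* `analysis/` — the numbered workflow scripts.
* `vignettes/takin-camera-trap-methods.Rmd` — models, assumptions,
  parameter choices and limitations.
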