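# riverload

Inverse modelling of diffuse chemical emissions on stream networks, and the
forward pipeline that turns calibrated emission factors into emission
inventories, river concentrations, loads to the sea and prediction-rate
verification against quality-standard exceedances.

## Who this is for

Environmental modellers and regulators who need a first, parsimonious
screening of where a chemical's diffuse emissions come from and where its
concentrations are likely to exceed environmental quality standards (EQS),
using only a stream network with travel times, a spatial *emission pattern*
(population, agricultural land, livestock, treatment-connected population,
or bare catchment area) and sparse river monitoring data.

## The model

Diffuse emission intensity at any point is assumed proportional to an
emission pattern EP with a uniform emission factor ε (e.g. ng per person
per second). During downstream transport the chemical dissipates first-order
over the water travel time *t* with an overall half-life DT50, so the load
at a river section *x* is the catchment integral

    L(x) = Σ_{i ∈ A(x)} ε · EP(i) · exp( −ln2 · t(i→x) / DT50 )

Dividing by ε gives the **load proxy** Φ(x), which carries the pattern's own
units. "Observed loads" are built as measured concentration × discharge, one
per sampling record. For each of 4 patterns × 9 DT50 values
{1, 3, 5, 7, 10, 20, 50, 100, 1000} days (36 proxies), observed loads are
regressed on the proxy by weighted least squares with weights √load; the
combination closest to the ideal point (R² = 100 %, intercept = 0) in the
normalised intercept/R² plane identifies the pattern and DT50, and the slope
of that fit — the intercept is ignored — estimates ε, with a 1000-iteration
record-level bootstrap for its confidence interval. Point-source emissions
propagate with the same decay kernel (indicators Z and W flag reaches where
they rival diffuse loads). Concentrations follow as C = L/Q with
annual-average flow Q from the Budyko water balance, and model skill is
checked with prediction-rate (ROC) curves: the cumulative fraction of
reported EQS exceedances captured while walking the sub-basins sorted by
decreasing concentration.

A seeded synthetic-data module generates networks, patterns, truth,
noisy observations, facilities and exceedance reports so that the whole
pipeline runs and is tested at desk scale without any external dataset.

## Worked example

```r
library(riverload)
sc  <- synthetic_scenario(seed = 42, n_reaches = 300, n_stations = 60)
sim <- simulate_scenario(sc)          # truth: EF = 10 ng/ind/s, DT50 = 10 d
loads   <- compute_observed_loads(
             sim$observations[sim$observations$substance == "popchem", ])
proxies <- build_proxy_grid(sim$network)
cal     <- grid_calibrate(proxies, loads, assumed_pattern = "pop")
print(cal)
#> <calibration_result>
#>   selected proxy : pop @ DT50 = 10 d (modelled 10 d)
#>   emission factor: 11.3581 ng/s per unit of 'pop'
#>   R^2 = 0.6833, intercept = 11416 ng/s, distance = 0.3176, n = 456
```

The true half-life (10 d) is identified and the emission factor (true value
10) is recovered within the sampling noise; the bootstrap interval covers
it:

```r
idx <- match(cal$observed_loads$reach_id, rownames(proxies))
ci  <- bootstrap_uncertainty(proxies[idx, "pop_dt10"],
                             cal$observed_loads$load_ng_s,
                             n_boot = 1000, seed = 1)
#> bootstrap 95% CI for the emission factor: [9.59, 13.30] ng/ind/s
```

Forward products — concentrations, exceedance prediction and sea loads:

```r
Q    <- accumulate_discharge(sim$network)
conc <- concentration(cal$emission_factor *
          accumulate_decayed(sim$network, cal$pattern, cal$selected_dt50), Q)
ex   <- sim$exceedances[sim$exceedances$substance == "popchem", ]
prediction_rate_curve(unname(conc), ex$exceed_aa == 1)
#> <prediction_rate_curve> n = 300, exceedances = 45, AUC = 1
#>   rates: rate_10 = 66.7 %, rate_20 = 100 %, rate_50 = 100 %
sea_loads(sim$network, list(popchem = cal$emission_factor *
  accumulate_decayed(sim$network, cal$pattern, cal$selected_dt50)))
#>   sea_id substance load_tonnes_y
#> 1  sea_1   popchem      0.093568
```

Reading: 45 of 300 sub-basins exceed the annual-average EQS in the synthetic
truth; ranking sub-basins by the calibrated model's concentration captures
66.7 % of them within the top 10 % and all of them within the top 20 %
(AUC = 1 because the calibrated model ranks reaches exactly like the truth
it was recovered from). The calibrated substance delivers 0.094 t/y to the
sea after in-stream dissipation.

## Command line

```sh
Rscript inst/cli/riverload.R run --config inst/extdata/demo_config.json \
        --seed 1 --outdir demo_out
```

Subcommands `simulate`, `proxy`, `calibrate`, `concentrations`,
`indicators`, `roc`, `inventory`, `run`; every run writes CSV outputs plus a
`manifest.json` with config echo and file checksums, and reruns are
byte-identical.

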