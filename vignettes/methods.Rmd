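---
title: "Methods: inverse emission-factor estimation on stream networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverse emission-factor estimation on stream networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverload)
```

## The model and its assumptions

`riverload` implements a deliberately parsimonious screening model of
chemical fate in river networks. Its assumptions are:

1. **Proportional diffuse emissions.** The emission intensity of a substance
   at any point is `ε · EP`, where EP is a known spatial emission pattern
   (population, agricultural area, livestock units, treatment-connected
   population, or bare catchment area) and ε a *uniform* emission factor.
   Everything spatial about emissions is carried by the pattern; everything
   substance-specific by the single scalar ε.
2. **Stationarity.** Emissions and travel times are constant in time.
3. **First-order dissipation over travel time.** All loss processes
   (degradation, volatilisation, settling, ...) are lumped into one overall
   half-life DT50, applied exponentially over the water travel time from
   source to evaluation point. Only the dissolved phase is modelled.
4. **Loads add linearly** along the network; point sources use the same
   decay kernel from their facility reach.

The load at reach *x* is the decayed catchment sum implemented by
`accumulate_decayed()`; dividing by ε gives the *load proxy* Φ, the
explanatory variable of the calibration. The inverse step treats (pattern,
DT50) as a discrete grid — 4 patterns × 9 half-lives
{1, 3, 5, 7, 10, 20, 50, 100, 1000} d = 36 proxies, optionally plus a
uniform (catchment-area) pattern — and estimates ε as a regression slope.
There is deliberately no continuous DT50 optimisation: half-lives inferred
this way are statistical summaries, not physical measurements, and the
coarse grid makes that explicit.

### Discretisation convention

The continuous catchment integral does not fix how a discrete reach
contributes to itself. We evaluate loads at each reach's *downstream node*
and let emissions enter at its *upstream end*: the path time from source
reach *i* to evaluation reach *x* includes the travel times of both
endpoints, and a reach's own emission is decayed over its own travel time
(`T(x→x) = travel_time(x)`). This is one admissible reading; it is applied
identically in the forward model, the proxies and the synthetic truth, so
calibration and generation can never disagree about the convention. Lake
and reservoir residence is folded into the reach travel time, which is an
input, not something the package derives.

## The calibration step

Observed loads are concentration × discharge, one per sampling record —
records are never averaged per station, because every record is one member
of the statistical population the regression sees. Weighted least squares
with weights `√load` regresses observed loads on each proxy (weights use
the *observed* load, not fitted values, so zero-load records are dropped).
The best proxy minimises the Euclidean distance from the ideal point
(R² = 100 %, intercept = 0) in the intercept/R² plane; the slope of that
fit is ε and its intercept is ignored in all downstream products.

Two genuinely open choices were closed as follows:

* **Intercept normaliser.** A "normalised" distance needs a scale for the
  intercept axis. We divide the intercept by the mean observed load, making
  both axes dimensionless and O(1); `normalizer = "sd_load"` is available
  for sensitivity analysis. This is the single most consequential free
  choice in the package and is therefore an explicit argument.
* **Weighted or unweighted R².** R² is computed from the weighted residual
  and total sums of squares about the weighted mean (what `summary.lm`
  reports for a weighted fit), clipped to [0, 1].

* **Assumed pattern.** Accumulated patterns are strongly collinear across
  catchments (all of them grow with drainage area), so under realistic
  noise the *free* ideal-point search may land on a neighbouring pattern
  whose proxy scale differs by orders of magnitude — and with it the slope.
  Practice is therefore to fix the pattern a priori from how the substance
  is used (population for household chemicals, agricultural land for
  pesticides) and let the grid search choose only the half-life within that
  pattern, while the best pattern overall is still reported for reference
  (`grid_calibrate(..., assumed_pattern =)`). With noiseless data the free
  search recovers the generating combination exactly; with σ = 0.3
  multiplicative noise and 500 records the assumed-pattern emission factor
  has a median absolute error around 10–15 % in the bundled scenarios,
  whereas the free search does not degrade gracefully.

Uncertainty comes from a record-level bootstrap (1000 iterations by
default, percentile 2.5/97.5 intervals, seeded and reproducible). Records,
not stations, are resampled, consistent with pooling all loads into one
population. When the statistically optimal DT50 is physically implausible,
`apply_dt50_override()` re-reads ε at an expert-chosen grid value and
reports the R² drop so the user can verify the fit did not deteriorate
significantly; both the modelled and the overridden DT50 are retained.

## Hydrology and forward products

Annual-average flow uses the classic Budyko relation
`AET/P = √(φ·tanh(1/φ)·(1 − e^(−φ)))`, φ = PET/P. The literature contains
several Budyko-type curves; only "the Budyko equation" being specified, the
classic form sits behind a single function boundary (`budyko_runoff()`) so
it can be swapped without touching the accumulation. Local runoff volumes
accumulate downstream without decay, so discharge is conserved at
confluences; concentrations are `C = L/Q` (annual averages only — no
seasonal mode), and the load/discharge/concentration triangle is exact by
construction. Emission inventories aggregate `pattern × ε` by reporting
district *without* decay (decay acts on loads in transit, not on emissions
at source), and sea loads are the decayed loads at outlet reaches; point
sources are decayed from their facility reach, not added at the outlet —
the alternative reading would only increase sea loads and is not
implemented.

## Verification

`prediction_rate_curve()` sorts sub-basins by decreasing concentration and
accumulates the fraction of reported exceedances captured. Decisions the
underlying description leaves open:

* **Ties.** Sub-basins with identical concentration form one block whose
  exceedances accrue proportionally (average-rank treatment); the curve is
  then independent of input order, and the all-tied degenerate case is the
  diagonal by construction.
* **Rates at 10/20/50 %** are linear interpolations between curve vertices.
* **AUC** is reported as the standard rank-based ROC area (Mann–Whitney
  with tie correction): 1 for a perfect predictor, 0.5 under independence.
  The area under the fraction-considered curve itself would max out at
  `1 − prevalence/2` and was rejected because it conflates skill with
  prevalence.
* **Multiple reports per sub-basin** count once: the unit is the sub-basin,
  not the report.
* The observed-concentration variant restricts everything to monitored
  sub-basins and returns an explicit *no-curve* object when no flagged
  sub-basin is monitored.

Percentile comparison of modelled vs observed concentrations restricts the
modelled population to the drainage-area range of the monitored reaches,
since small headwaters are systematically unmonitored and would bias the
modelled distribution low.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *statistical* structure the method assumes:
random in-trees (preferential attachment to low-order reaches, giving
dendritic branching) of 10²–10⁴ reaches with ~7 km² lognormal sub-basins;
lognormal travel times (mean 0.2 d per reach, so typical source-to-outlet
times span the lower half of the DT50 grid); lognormal population with a
5 % "urban" subset scaled ×20; agriculture as a uniform 10–60 % fraction of
local area; livestock and connected population as noisy transforms of
those; multiplicative lognormal observation noise (median-unbiased,
σ = 0.3 by default, matching a factor-of-10 verification framing);
stations weighted toward large drainage areas; sparse lognormal
facilities; and exceedance flags thresholded from the truth with optional
label noise. EQS defaults (0.2/1.8 and 0.6/2.0 µg/L) are in the range
typical of regulated priority substances, and true emission factors
(10 ng/ind/s, 200 ng/km²/s) sit inside the span of published inverse
estimates.

It does **not** emulate real European geography, country borders, actual
substance chemistry, seasonal hydrology, or spatially correlated reporting
practices. A green test therefore establishes that the *algorithms* are
correct and that the inverse step recovers a world that satisfies the
model's own assumptions — not that the model describes any real river
basin. By default the synthetic truth excludes point-source loads
(`include_points_in_truth = FALSE`), mirroring the assumption that
calibration sites are unaffected by point sources; switching it on lets a
user study exactly how that assumption fails.

Determinism: every generator draws from Mersenne–Twister under
`withr::with_seed`, with per-stage sub-seeds derived from the master seed,
so each stage is individually reproducible and identical across platforms.

## Numerical choices and degenerate inputs

* Unit constants are fixed once (1 y = 3.15576e7 s; ng/s × 3.15576e-5 =
  kg/y; tonnes = 10³ kg) and tested.
* `dt50 = Inf` is an accepted sentinel: the decay term is exactly 1, which
  makes discharge accumulation and the uniform pattern share the decayed
  accumulation code path, and conservation holds to 1e-12.
* Zero-variance proxies, fewer than 3 usable observations, nonpositive
  weights, cycles in the downstream graph, unknown reaches and negative
  inputs all raise immediate, named errors; nonpositive discharges are
  skipped with a warning and counted, and `usable + skipped + censored`
  always equals the input record count.
* Below-LOQ records are excluded by default (calibration uses quantifiable
  observations); LOQ/2 and zero substitution are available for sensitivity
  runs, never silently.
* Reaches with zero diffuse load but positive point load get `Z = Inf`
  with a flag rather than being dropped.
* Tie-breaks in proxy selection (equal distance → higher R² → smaller
  DT50) and in station snapping (equal distance → larger drainage area)
  are deterministic and tested.

## Known limitations

* Single-pattern regression only; no joint multi-pattern fits.
* Annual averages throughout; event dynamics and seasonality are out of
  scope, as is particulate-phase transport.
* The bootstrap quantifies sampling uncertainty of the regression, not
  structural uncertainty of the pattern/DT50 grid choice.
* Station snapping is node-based Euclidean; networks are topological
  objects here, with no geometry beyond the embedding the generator
  provides.
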