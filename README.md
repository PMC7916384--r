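# wheatDA

Winter-wheat yield estimation by ensemble Kalman filter (EnKF) data
assimilation of remotely sensed leaf area index (LAI) and surface soil
moisture.

`wheatDA` is for agro-ecosystem modellers and remote-sensing scientists who
want to study *how* assimilating optical and radar retrievals into a daily
crop model changes regional yield estimates under different water-supply
regimes — and which observation strategy (LAI alone, soil moisture alone, or
both jointly) pays off where. Because the satellite scenes and field
campaigns such studies rest on are rarely published, the package ships a
synthetic-scene generator so that the whole analysis runs as a *twin
experiment*: truth is simulated, scenes are rendered from it, and every
estimate can be scored against the truth it came from.

## The method

**Crop model.** A reduced-order daily winter-wheat simulator tracks thermal
time and phenophase (green-up, jointing, heading–filling, milking, maturity
via growing-degree-day thresholds), logistic LAI growth under water stress
with post-milking senescence, a seven-layer cascading-bucket soil water
balance (0–10 … 160–200 cm) with radiation-based potential ET, and
light-interception biomass, closed by `yield = harvest_index × biomass` at
maturity. It exposes exactly the states the filter needs: LAI and layered
soil moisture.

**Retrieval.** Optical scenes give NDVI and NDWI; canopy water content
follows the quadratic `m_veg = 1.44·NDWI² + 1.36·NDWI + 0.34` (kg m⁻²).
Radar scenes are inverted through the water cloud model

    σ⁰_can = A·m_veg·cosθ·(1 − γ²) + γ²·σ⁰_soil,   γ² = exp(−2·B·m_veg·secθ)

with winter-wheat parameters A = 0.0018, B = 0.138 (linear power units).
Site-calibrated linear regressions map NDVI → LAI and soil backscatter (dB)
→ volumetric soil moisture.

**Assimilation.** A stochastic (perturbed-observation) EnKF,

    Aᵃ = Aᶠ + P Hᵀ (H P Hᵀ + R)⁻¹ (D − H Aᶠ),

propagates an ensemble of model states day by day and updates it on scene
dates. Relative error levels: 17% / 9% for modelled LAI / soil moisture and
13% / 8% for the retrievals. The joint strategy stacks LAI and 0–20 cm
moisture into one observation vector so ensemble cross-covariances couple
canopy and water updates.

**Yield mapping.** Assimilated trajectories are collapsed into
stage-weighted composites (LAI weights 0.0550 / 0.2650 / 0.5660 / 0.1140 and
soil-moisture weights 0.0555 / 0.5655 / 0.2605 / 0.1185 over green-up,
jointing, heading–filling, milking), regressed on measured site yields per
water regime, validated on held-out sites (RMSE and mean absolute relative
error), and applied per pixel. A multi-date NDVI decision tree masks winter
wheat; terrain (< 600 m and < 15° slope) splits it into irrigated and
rain-fed regimes.

## Worked example

```r
library(wheatDA)

res <- run_pipeline(pipeline_config(seed = 1))
print(res)
```

```
wheat_pipeline: 45 sites, strategies LAI_only/SM_only/joint (20.0 s)
  retrieval: LAI R2 0.95 RMSE 0.40 | SM R2 0.86 RMSE 0.0188
strategy comparison (rank 1 = recommended):
     regime strategy     rmse       are         r2 n_cal n_val rank   tie
1 irrigated    joint 791.6585  7.310988 0.47416530    10    15    1 FALSE
2 irrigated LAI_only 812.3643  7.667234 0.38595685    10    15    2 FALSE
3 irrigated  SM_only 868.7995  8.318599 0.01549678    10    15    3 FALSE
4  rain_fed    joint 526.7607  6.378640 0.58342260    10    10    1 FALSE
5  rain_fed  SM_only 542.8865  7.431923 0.39806561    10    10    2 FALSE
6  rain_fed LAI_only 864.1295 10.463586 0.35069488    10    10    3 FALSE
  irrigated: use joint
  rain_fed: use joint
```

The printed table is the validation error of each assimilation strategy in
each water regime: `rmse` (kg ha⁻¹) and `are` (%) of predicted vs measured
yields on the held-out sites, ranked per regime. The recommendation line is
the regional mapping rule — the model each regime's pixels get when
`res$yield_map` is composed. A single season is noisy (here the joint model
edges LAI-only in the irrigated regime by ~3%); the replicated twin
experiment below is the statistically meaningful comparison. Over
replicates, LAI alone is typically best or tied in the irrigated regime,
while under rain-fed water stress the water-informed strategies lead and
LAI alone is weakest.

The replicated twin experiment scores the filter itself against synthetic
truth:

```r
tw <- twin_experiment(pipeline_config(seed = 1), n_replicates = 20)
print(tw)
```

```
twin_experiment: 20 replicates
  assimilated LAI beat open loop in 100% of replicates; SM in 100%
  yield RMSE medians (q25-q75) by regime x strategy:
     regime strategy median   q25   q75 are_median
1 irrigated    joint  873.3 823.4 926.7      7.501
2  rain_fed    joint  747.9 657.8 788.7      8.640
3 irrigated LAI_only  854.6 805.7 900.7      7.605
4  rain_fed LAI_only  773.7 664.0 889.7      9.742
5 irrigated  SM_only  878.8 840.4 937.8      8.049
6  rain_fed  SM_only  703.2 619.3 812.8      8.410
```

## Layout

- `R/crop_model.R` — daily growth and soil-water simulator
- `R/retrieval.R` — indices, water cloud model, linear retrievals
- `R/assimilation.R` — ensemble generation, EnKF update, assimilation runs
- `R/yield_mapping.R` — stage composites, yield regressions, validation
- `R/area_classification.R` — wheat mask and irrigated/rain-fed split
- `R/synthetic_data.R` — scenario generator (weather, truth, scenes, sites)
- `R/pipeline.R` — end-to-end orchestration and the twin-experiment harness
- `R/grid.R` — matrix-backed rasters with ESRI ASCII grid I/O
- `vignettes/methods.Rmd` — the model, its assumptions, and design choices
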