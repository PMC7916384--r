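---
title: "Methods: crop-model data assimilation for winter wheat yield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crop-model data assimilation for winter wheat yield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatDA)
```

# What the package computes

`wheatDA` estimates regional winter-wheat yield by assimilating remotely
sensed leaf area index (LAI) and surface soil moisture into a daily
crop-growth model with an ensemble Kalman filter (EnKF), then regressing
measured site yields on stage-weighted composites of the assimilated states,
separately for irrigated and rain-fed growing areas. Because studies of this
kind rest on unpublished satellite scenes and field campaigns, the package
is built around *twin experiments*: a synthetic-scene generator simulates a
known truth, renders optical and radar scenes from it, and every downstream
estimate can be scored against that truth.

This vignette documents the models, their assumptions, the tunable
parameters, and the design decisions taken where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

# The crop model

The simulator is deliberately reduced-order: it carries exactly the state
the filter observes (LAI and layered soil moisture) plus what the yield
closure needs (thermal time, phenophase, biomass). It is not, and does not
claim to be, numerically equivalent to a full cropping-system model; it is a
transparent stand-in with the same observable states.

**Phenology.** Thermal time accumulates as `max(0, (tmax + tmin)/2 −
base_temp)` with base 0 °C. Five growing-degree-day thresholds (600, 860,
1050, 1450, 2100 °C·d) mark entry into green-up, jointing, heading–filling,
milking and maturity. For a mid-October sowing under the default climate
they land on a mid-February green-up, early-April jointing, mid-April
heading, early/mid-May milking and a mid-June maturity, with the LAI peak
about 205 days after sowing — the calendar of winter wheat in a
warm-temperate semi-arid setting.

**Canopy.** LAI starts at `lai_init = 0.5` (the autumn-tillered canopy
carried through dormancy), grows logistically from green-up until milking at
relative rate `rgr·stress` towards `lai_max` (defaults 0.065 d⁻¹ and
7 m² m⁻²), then senesces exponentially at 0.08 d⁻¹. The senescence rate is
set so that a harvested/ripe field drops below the NDVI = 0.25
classification threshold by the June scene.

**Soil water.** Seven layers (0–10, 10–20, 20–50, 50–80, 80–120, 120–160,
160–200 cm) with per-layer field capacity, wilting point and saturation
(defaults 0.34 / 0.10 / 0.46 cm³ cm⁻³, a deep loess profile). Each day:
rain plus irrigation infiltrates the top layer and excess above field
capacity cascades downward, with bottom-layer excess leaving as drainage;
evapotranspiration demand is a radiation-based (Priestley–Taylor-style)
potential — slope-of-saturation-curve term at the daily mean temperature,
net radiation taken as 75% of global radiation — multiplied by the stress
factor, the `et_coeff` (0.9), and a canopy cover factor
`0.35 + 0.65·(1 − e^{−k·LAI})` that keeps dormant-season ET realistic
(soil evaporation under sparse cover is supply-limited). Extraction is
partitioned over the rooted layers by thickness, and roots deepen with
thermal time (`20 + 0.09·gdd` cm, capped at the profile). The balance
closes to 10⁻⁹ mm per day by construction, and the tests assert it.

**Stress.** The stress factor ramps linearly from 0 at wilting point to 1 at
field capacity, evaluated over the *current root zone*. A deep-rooted crop
buffers short dry spells; the 0–20 cm observation depth still reaches the
stress term both directly (those layers are in the root zone) and through
ensemble cross-covariances that update deeper layers.

**Yield.** Biomass accumulates as `rue·srad·(1 − e^{−k·LAI})·stress·10`
kg ha⁻¹ d⁻¹ (RUE 1.3 g MJ⁻¹, extinction 0.6) between green-up and maturity;
yield is `harvest_index × biomass` (0.45) at maturity. Nitrogen and carbon
dynamics are intentionally out of scope: the filter assimilates only canopy
and water states.

# Retrieval operators

NDVI and NDWI are the usual normalized differences; pixels whose denominator
vanishes (or that are nodata) stay nodata throughout. Canopy water content
follows the quadratic `m_veg = 1.44·NDWI² + 1.36·NDWI + 0.34` (kg m⁻²),
clamped at zero. The water cloud model splits total backscatter into direct
canopy scattering and soil scattering attenuated twice by the canopy; its
inverse is algebraic, and pixels whose two-way attenuation falls below 10⁻⁶
(very dense canopy, no soil signal) are masked rather than extrapolated.

Unit convention: the water cloud model operates in **linear power**; scene
files carry dB, and conversions are explicit operations. The linear
soil-moisture regression is applied to soil backscatter in **dB** — its
coefficient scale only produces plausible moisture (≈0.1–0.35 cm³ cm⁻³) for
negative dB-scale inputs. The incidence angle defaults to a fixed 39°
(mid-swath typical). Linear retrievals extrapolate, so predictions are
clamped to physical ranges: LAI ≥ 0, soil moisture in [0, 0.6] cm³ cm⁻³.

Retrieval calibration pools the two field-campaign dates (jointing and
heading–filling), each paired with its temporally nearest scene. With a
single date the synthetic sites — which share one sowing date and climate,
and hence are phenologically synchronized — span too little of the LAI range
to constrain the regression slope, and a misestimated slope extrapolates
badly to peak canopy. Real campaigns spread across heterogeneous terrain do
not have this degeneracy; pooling restores the spread the regression needs.
Calibration predictors are extracted as *field means* of the relevant
raster, as a plot campaign pairs averaged subsamples with the local scene
statistic; the per-site *observation series* that feed the filter instead
come from the single imaging pixel at the site coordinates, as an
operational system extracts them, so pixel-scale retrieval noise is part of
the observation error the filter must handle.

Observation error follows the configured relative SDs (13% LAI, 8%
moisture) but is floored at the retrieval model's own calibration RMSE —
the *measured* accuracy of the retrieval. The floor matters early in the
season: a relative error on a small LAI wildly understates the absolute
pixel error there, and a filter that over-trusts those observations
suppresses the young canopy and carries the deficit through the entire
logistic growth phase.

# The ensemble Kalman filter

The filter is the stochastic, perturbed-observation EnKF: each member's
innovation uses its own observation draw `N(value, sd²)`, the forecast
covariance is the ensemble sample covariance, and the gain is
`P Hᵀ (H P Hᵀ + R)⁻¹`. A deterministic unperturbed-observation variant is
exposed for hand-checkable unit tests; it understates analysis spread and is
not used in production runs.

Error levels are relative: 17% (modelled LAI), 9% (modelled soil moisture),
13% (retrieved LAI), 8% (retrieved soil moisture). Perturbations are
multiplicative, `x·(1 + ε)`, because the error levels are percentages of the
state. When an observation arrives without an explicit error, its SD is
`relative SD × value`, floored at 0.01 in the observation's units so
near-zero values never produce a zero-variance observation; the pipeline
supplies explicit SDs floored at the measured retrieval RMSE, as described
above.

Three design choices deserve explanation:

* **Spread refreshment.** The model-error perturbation is applied to the
  forecast ensemble at *every* observation time, not only at
  initialization. A perturb-once ensemble collapses after the first update
  (this model's dynamics are strongly contracting), after which later
  observations are ignored; refreshing the spread keeps the filter's trust
  in the model at the stated 17%/9% level throughout the season.
* **Joint state vector.** The joint strategy stacks LAI and all seven
  moisture layers into one state with a two-row observation operator (an
  LAI selector and a thickness-weighted 0–20 cm aggregator). Ensemble
  cross-covariances then let a moisture observation adjust the canopy and
  vice versa — this coupling is precisely what distinguishes joint
  assimilation from running the two single-variable filters side by side.
* **Clamp-after-update.** Analysis states are clamped to physical bounds
  rather than rejected: moisture to [0, saturation] per layer, LAI to
  [0, 1.5·lai_max]. The headroom above the nominal canopy cap matters:
  when the true canopy runs above the model's parameterization (the
  regional-calibration bias the filter exists to correct), a clamp at
  `lai_max` would forbid the observations from ever lifting the analysis
  to the truth. Clamp events are counted and reported.

Yield from an assimilated run is taken from each member's own biomass
integration (ensemble mean reported); the regional yield *maps* instead go
through the stage-composite regressions below, which is the route the
validation metrics score.

# Stage weights and yield models

Four growth stages contribute to yield with fixed weights (LAI:
0.0550 / 0.2650 / 0.5660 / 0.1140; soil moisture:
0.0555 / 0.5655 / 0.2605 / 0.1185 for green-up / jointing /
heading–filling / milking). Both sets sum to one, which is asserted at
construction; the analytic-hierarchy derivation behind them is out of scope
— they are configuration with those defaults. Stage values are sampled from
the assimilated daily trajectory on the scene dates nearest each stage
midpoint (optical dates for LAI, radar dates for moisture).

Per regime and strategy, measured calibration-site yields are regressed on
the composites (one predictor for the single-variable strategies, two for
joint) by ordinary least squares, with model significance classed
*/**/*** at 0.05/0.01/0.001. Validation reports RMSE and ARE, where **ARE
is defined as the mean of per-site absolute relative errors, in percent** —
the quantity is not otherwise standardized, and alternatives (relative error
of totals) exist, so the definition is worth stating prominently.
`compare_strategies()` ranks by RMSE, breaking ties by ARE and then by a
fixed strategy order (flagged), and names a recommended strategy per regime.

For regional maps, the per-site assimilated stage values are extended to
rasters by a per-stage OLS regression from the retrieved raster value to the
assimilated value across calibration sites — the functional form of this
scale transfer is an interpretation (the procedure it mirrors is described
only loosely in the literature), and it is isolated in one helper so an
alternative can be substituted.

# Classification

A pixel is winter wheat when NDVI exceeds 0.25 in mid-March and mid-April,
is below 0.25 in June, and declines from April to June (threshold
configurable). Wheat pixels below 600 m elevation with slope below 15° are
irrigated; **all other wheat pixels are rain-fed**. The complement rule is a
deliberate choice: defining rain-fed as "above 600 m *and* steeper than 15°"
leaves pixels like (500 m, 20°) unlabeled, so the package labels every wheat
pixel and documents the discrepancy here. Slope is derived from the DEM by
central finite differences when not supplied; synthetic terrain supplies it
directly.

# The synthetic scenario

The generator's defaults are the study conditions, chosen once:

* **Season and climate.** Sowing 10 October, season to 30 June. Temperature
  is an annual sinusoid (mean 13 °C, amplitude 12 °C, 1.5 °C daily noise,
  ±5 °C diurnal range); radiation a matching sinusoid; rainfall a Bernoulli
  process (rate 0.14 d⁻¹, mean depth 6 mm) whose rate drops to a quarter
  from 1 May — the pre-monsoon late spring of the target climate is
  markedly drier than winter and early spring, which is what exposes
  rain-fed grain fill to drought while leaving canopy formation largely
  unharmed. Seasonal totals land near 170 mm; in a semi-arid monsoon
  climate with 450–600 mm annual rainfall the winter wheat season receives
  roughly a third of the annual total.
* **Fields and sites.** 45 fields (25 irrigated, 20 rain-fed) on a 63×63
  grid of 1-ha pixels, one sampling site per field; calibration/validation
  split 10/15 irrigated and 10/10 rain-fed, drawn under the scenario seed.
  Irrigated fields sit on a 400 m valley floor (slope 3°), rain-fed fields
  on a 750 m upland (8°), so the terrain rule recovers the regime layout
  exactly.
* **Heterogeneity.** A per-field fertility factor (SD 7%) scales canopy
  potential and radiation-use efficiency together — soil quality drives
  both in real fields, and this coupling is what makes canopy observations
  informative about yield. Water-holding capacity varies by texture:
  valley alluvium narrowly (field capacity multiplier 1.05 ± 0.035), upland
  soils widely (0.96 ± 0.22), with the wilting point held fixed so
  *plant-available* water genuinely differs between fields. At sowing every
  profile stands at 97% of its own field capacity: the deep loess store
  recharges during the summer monsoon, so the water a rain-fed crop will
  ration through grain fill is set by texture, not by initial luck.
  Rain-fed yield therefore depends on both fertility and water supply;
  irrigated yield essentially on fertility alone. That asymmetry is the
  mechanism behind the strategy comparison: surface moisture carries
  yield-relevant signal only where water limits growth.
* **Model–truth mismatch.** True canopy potential runs 30% above the
  nominal model parameterization (`truth_bias`). This encodes the familiar
  situation of a regionally calibrated crop model under-predicting local
  canopies by a wide margin — open-loop LAI errors of well over half a
  unit are typical of regional applications — and it is the error the
  assimilation exists to correct; without it a twin experiment's open loop
  is unrealistically close to truth and there is nothing for the filter to
  fix.
* **Irrigation.** Nine events (≈565 mm) from a late-November winter
  irrigation through early June, spaced so irrigated fields never drop
  below stress 0.8 during the scored stages; rain-fed fields receive none
  and show stress episodes every season.
* **Scenes.** Radar on a 12-day cadence at 39° incidence; seven optical
  dates (late February to the post-harvest June scene), any of which can be
  declared cloud-masked and renders fully nodata. Scenes are rendered
  through the *inverse* of the retrieval equations — NDVI from truth LAI,
  canopy water as `0.34 + 0.35·LAI` (saturating at the NDWI = 1 ceiling of
  the polynomial), soil backscatter from truth 0–20 cm moisture through the
  inverted linear retrieval, forward water cloud model on top — plus
  Gaussian noise: reflectance SD 0.025, backscatter SD 2.0 dB, which
  produce pixel-level retrieval errors near 1 m² m⁻² (LAI) and
  0.03 cm³ cm⁻³ (moisture), the accuracy class of current sensor
  retrievals (`target_lai_rmse`, `target_sm_rmse` record the intended
  values).
  Field measurements add noise of 0.4 m² m⁻² (LAI), 0.02 cm³ cm⁻³
  (moisture) and 300 kg ha⁻¹ (yield).
* **What rendering through the inverse buys and costs.** Because scenes are
  generated by the same equations retrieval inverts, zero-noise
  render/retrieve round trips are exact to 10⁻⁶ — retrieval is
  self-consistent *by construction*, which deliberately isolates the
  assimilation and yield stages as the scientifically tested components.
  The cost is realism: passing tests say nothing about radiative-transfer
  adequacy, speckle, terrain effects on backscatter, or retrieval-model
  misspecification on real scenes. A `render_mismatch` knob perturbs the
  rendering coefficients for studying retrieval bias, and defaults to 0.

# Numerical choices and degenerate inputs

Weather gaps fail loudly with the missing date named; degenerate soil
profiles (wilting point ≥ field capacity), constant or collinear regression
predictors, empty wheat masks, all-nodata scenes, single-pair validations
and out-of-range NDWI are rejected rather than silently accommodated. A
singular innovation covariance is regularized by a small ridge on R and
logged. Strategy ties are broken deterministically and flagged. Index
computations mask near-zero denominators at 10⁻¹².

Problem sizes were chosen at desk scale: a 63×63-pixel grid, 45 fields, a
100-member ensemble, and 20-replicate twin experiments, which together keep
a full replicated experiment in the minutes range on one core. Pipeline
tests use a 24×24 grid with 12 fields and a 40-member ensemble.

# Known limitations

* The crop model is a surrogate: no nitrogen or carbon balance, no cultivar
  genetics, no frost or heat damage; phenology is purely thermal.
* The scene generator is statistically, not radiometrically, realistic (no
  PROSAIL-class radiative transfer, no speckle statistics, no topographic
  backscatter effects).
* The stage weights and retrieval coefficients are taken as given
  configuration; the package does not re-derive them.
* Twin-experiment conclusions transfer to real data only insofar as the
  scenario's mechanisms (fertility–canopy coupling, texture-driven water
  supply, model canopy bias) describe the target region.
* Parameter (as opposed to state) estimation, variational assimilation,
  localization and inflation are out of scope.
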