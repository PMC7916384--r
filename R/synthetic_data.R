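#' Synthetic scenario configuration
#'
#' Defines one simulated winter-wheat season: grid and field layout, the
#' irrigated / rain-fed mix, weather statistics, satellite revisit dates,
#' and noise levels for scenes and field measurements. Defaults are a
#' desk-scale analogue of a warm-temperate semi-arid wheat region: a
#' mid-October sowing, seasonal rainfall around 280 mm (the growing-season
#' share of a 450-600 mm annual regime), a 12-day SAR revisit, a handful of
#' cloud-free optical scenes, and one sampling site per field with 25
#' irrigated and 20 rain-fed sites (45 in all).
#'
#' @param seed integer seed; all scenario randomness derives from it.
#' @param n_fields number of wheat fields (one sampling site per field).
#' @param frac_irrigated fraction of fields on irrigated (low, flat) terrain.
#' @param grid_n square grid edge, pixels.
#' @param cellsize pixel edge, m (100 m gives 1 ha pixels).
#' @param sowing_date,season_end season span (ISO dates).
#' @param t_mean,t_amp annual mean and amplitude of the temperature sinusoid,
#'   degC; `t_sd` day-to-day noise; `diurnal` half-range between tmax/tmin.
#' @param rain_rate daily rain probability; `rain_mean` mean event depth, mm.
#' @param late_rain_factor multiplier on the rain probability from
#'   `late_rain_from` onwards: the pre-monsoon late spring of the target
#'   climate is markedly drier than winter and early spring, which is what
#'   exposes rain-fed grain fill to drought.
#' @param late_rain_from date the dry late-season regime starts.
#' @param srad_mean,srad_amp seasonal solar radiation sinusoid, MJ m-2 d-1.
#' @param irrigation data.frame (`date`, `depth_mm`) applied to every
#'   irrigated field.
#' @param s1_dates SAR scene dates (default: 12-day cadence from mid
#'   February); `theta_inc` incidence angle, degrees.
#' @param s2_dates optical scene dates; `cloud_masked` subset rendered fully
#'   nodata.
#' @param refl_sd reflectance noise SD; `sar_sd_db` backscatter noise SD, dB.
#'   Defaults emulate scene-level retrieval accuracies near 1 m2 m-2 (LAI)
#'   and 0.03 cm3 cm-3 (soil moisture); see `target_lai_rmse`.
#' @param target_lai_rmse,target_sm_rmse the retrieval accuracy the noise
#'   defaults are meant to produce (documentation + test targets, not used
#'   in rendering).
#' @param meas_lai_sd,meas_sm_sd,meas_yield_sd field measurement noise SDs
#'   (m2 m-2, cm3 cm-3, kg ha-1).
#' @param nir_plus_red,mveg_per_lai rendering constants: total red+NIR
#'   reflectance, and canopy water content gained per unit LAI (kg m-2).
#' @param render_mismatch relative perturbation of the rendering coefficients
#'   (model-mismatch knob; 0 keeps render/retrieve exactly inverse).
#' @param field_cv relative SD of per-field variation in growth parameters
#'   and initial moisture (what makes sites differ).
#' @param truth_bias multiplicative offset of the true canopy potential above
#'   the nominal model parameterization: a regionally calibrated model run
#'   at nominal parameters under-predicts the canopy of most fields, which
#'   is the mismatch assimilation is there to correct.
#' @param init_theta nominal initial profile moisture, cm3 cm-3.
#' @param n_cal_irrigated,n_cal_rain_fed calibration-site counts per regime
#'   (the rest validate: 10/15 irrigated, 10/10 rain-fed by default).
#' @param meas_dates named measurement dates (jointing and heading-filling
#'   field campaign).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_fields = 45, frac_irrigated = 25 / 45,
                            grid_n = 63, cellsize = 100,
                            sowing_date = "2018-10-10",
                            season_end = "2019-06-30",
                            t_mean = 13, t_amp = 12, t_sd = 1.5, diurnal = 5,
                            rain_rate = 0.14, rain_mean = 6,
                            late_rain_factor = 0.25,
                            late_rain_from = "2019-05-01",
                            srad_mean = 15, srad_amp = 9,
                            irrigation = data.frame(
                              date = as.Date(c("2018-11-25", "2019-02-15",
                                               "2019-03-10", "2019-03-28",
                                               "2019-04-12", "2019-04-26",
                                               "2019-05-10", "2019-05-24",
                                               "2019-06-05")),
                              depth_mm = c(90, 60, 60, 60, 60, 60, 60, 60,
                                           50)),
                            s1_dates = seq(as.Date("2019-02-18"),
                                           as.Date("2019-06-18"), by = 12),
                            theta_inc = 39,
                            s2_dates = as.Date(c("2019-02-20", "2019-03-17",
                                                 "2019-04-01", "2019-04-16",
                                                 "2019-05-06", "2019-05-21",
                                                 "2019-06-10")),
                            cloud_masked = as.Date(character()),
                            refl_sd = 0.025, sar_sd_db = 2.0,
                            target_lai_rmse = 1.0, target_sm_rmse = 0.03,
                            meas_lai_sd = 0.4, meas_sm_sd = 0.02,
                            meas_yield_sd = 300,
                            nir_plus_red = 0.45, mveg_per_lai = 0.35,
                            render_mismatch = 0, field_cv = 0.07,
                            truth_bias = 1.3,
                            init_theta = 0.33,
                            n_cal_irrigated = 10, n_cal_rain_fed = 10,
                            meas_dates = c(jointing = "2019-03-17",
                                           heading_filling = "2019-04-19")) {
  stopifnot(frac_irrigated >= 0, frac_irrigated <= 1,
            all(c(refl_sd, sar_sd_db, meas_lai_sd, meas_sm_sd,
                  meas_yield_sd) >= 0),
            n_fields >= 2, grid_n >= 8)
  cfg <- list(seed = as.integer(seed), n_fields = n_fields,
              frac_irrigated = frac_irrigated, grid_n = grid_n,
              cellsize = cellsize,
              sowing_date = as.Date(sowing_date),
              season_end = as.Date(season_end),
              t_mean = t_mean, t_amp = t_amp, t_sd = t_sd, diurnal = diurnal,
              rain_rate = rain_rate, rain_mean = rain_mean,
              late_rain_factor = late_rain_factor,
              late_rain_from = as.Date(late_rain_from),
              srad_mean = srad_mean, srad_amp = srad_amp,
              irrigation = irrigation,
              s1_dates = as.Date(s1_dates), theta_inc = theta_inc,
              s2_dates = as.Date(s2_dates),
              cloud_masked = as.Date(cloud_masked),
              refl_sd = refl_sd, sar_sd_db = sar_sd_db,
              target_lai_rmse = target_lai_rmse,
              target_sm_rmse = target_sm_rmse,
              meas_lai_sd = meas_lai_sd, meas_sm_sd = meas_sm_sd,
              meas_yield_sd = meas_yield_sd,
              nir_plus_red = nir_plus_red, mveg_per_lai = mveg_per_lai,
              render_mismatch = render_mismatch, field_cv = field_cv,
              truth_bias = truth_bias,
              init_theta = init_theta,
              n_cal_irrigated = n_cal_irrigated,
              n_cal_rain_fed = n_cal_rain_fed,
              meas_dates = as.Date(meas_dates))
  names(cfg$meas_dates) <- names(meas_dates)
  all_dates <- c(cfg$s1_dates, cfg$s2_dates)
  if (any(all_dates < cfg$sowing_date | all_dates > cfg$season_end))
    stop("scene dates must fall inside the season")
  structure(cfg, class = "scenario_config")
}

#' Generate a season of daily weather
#'
#' Sinusoidal annual temperature and radiation cycles with Gaussian
#' day-to-day noise, and rainfall as a Bernoulli event process with
#' exponential depths. Reproducible under the scenario seed.
#'
#' @param cfg a [scenario_config()].
#' @return weather data.frame (`date`, `tmax`, `tmin`, `precip`, `srad`).
#' @export
generate_weather <- function(cfg) {
  set.seed(cfg$seed + 1L)
  dates <- seq(cfg$sowing_date, cfg$season_end, by = "day")
  doy <- as.integer(strftime(dates, "%j"))
  n <- length(dates)
  tmean <- cfg$t_mean + cfg$t_amp * cos(2 * pi * (doy - 196) / 365) +
    stats::rnorm(n, 0, cfg$t_sd)
  rate <- rep(cfg$rain_rate, n)
  rate[dates >= cfg$late_rain_from] <- cfg$rain_rate * cfg$late_rain_factor
  rain_day <- stats::runif(n) < rate
  precip <- ifelse(rain_day, stats::rexp(n, 1 / max(cfg$rain_mean, 1e-12)),
                   0)
  if (cfg$rain_rate == 0 || cfg$rain_mean == 0) precip[] <- 0
  srad <- pmax(1, cfg$srad_mean +
                 cfg$srad_amp * cos(2 * pi * (doy - 172) / 365) +
                 stats::rnorm(n, 0, 1.5) - 4 * rain_day)
  data.frame(date = dates, tmax = tmean + cfg$diurnal,
             tmin = tmean - cfg$diurnal, precip = precip, srad = srad)
}

# Rectangular field layout: fields occupy interior blocks of a square slot
# grid, leaving a background margin of non-wheat pixels.
field_layout <- function(cfg) {
  slots_per_side <- ceiling(sqrt(cfg$n_fields))
  slot <- floor(cfg$grid_n / slots_per_side)
  if (slot < 3) stop("grid too small for the requested number of fields")
  ids <- matrix(0L, cfg$grid_n, cfg$grid_n)
  centers <- matrix(NA_integer_, cfg$n_fields, 2)
  f <- 0L
  for (i in seq_len(slots_per_side)) {
    for (j in seq_len(slots_per_side)) {
      if (f >= cfg$n_fields) break
      f <- f + 1L
      r <- ((i - 1) * slot + 2):(i * slot - 1)
      c <- ((j - 1) * slot + 2):(j * slot - 1)
      ids[r, c] <- f
      centers[f, ] <- c(r[ceiling(length(r) / 2)], c[ceiling(length(c) / 2)])
    }
  }
  list(ids = ids, centers = centers)
}

#' Generate the synthetic truth for a scenario
#'
#' Lays out fields on the grid, assigns irrigated fields to low flat terrain
#' and rain-fed fields to high terrain, draws modest per-field variation in
#' growth parameters and initial moisture, and simulates every field's daily
#' truth with the crop model (irrigated fields receive the configured
#' irrigation schedule; rain-fed fields receive none, so under default
#' rainfall they experience water-stress episodes the irrigated fields do
#' not).
#'
#' @param cfg a [scenario_config()].
#' @return an object of class `wheat_scenario`: list with `cfg`, `weather`,
#'   `fields` (per-field data.frame: `field`, `regime`, `row`, `col`,
#'   `yield`, `min_stress`), `trajectories` (per-field `crop_trajectory`),
#'   `truth_lai` / `truth_sm` (day x field matrices over the season;
#'   post-maturity LAI is 0 = harvested, moisture holds its final value),
#'   `terrain`, `field_map`, `regime_mask` (the as-built regime raster),
#'   `stage_dates` (scenario-consensus stage midpoints), `soil`, `params`.
#' @export
generate_truth <- function(cfg = scenario_config()) {
  weather <- generate_weather(cfg)
  lay <- field_layout(cfg)
  n_irr <- round(cfg$frac_irrigated * cfg$n_fields)
  regime <- rep(c("irrigated", "rain_fed"),
                c(n_irr, cfg$n_fields - n_irr))

  set.seed(cfg$seed + 2L)
  soil <- soil_profile()
  base <- crop_params()
  cv <- cfg$field_cv
  # a per-field fertility factor scales canopy potential and conversion
  # efficiency together, as soil quality does in real fields; this is what
  # makes canopy observations informative about final yield
  quality <- 1 + stats::rnorm(cfg$n_fields, 0, cv)
  fparams <- lapply(seq_len(cfg$n_fields), function(f) {
    p <- base
    p$lai_max <- base$lai_max * quality[f] * cfg$truth_bias
    p$rue <- base$rue * quality[f] * (1 + stats::rnorm(1, 0, cv / 2))
    p$rgr <- base$rgr * (1 + stats::rnorm(1, 0, cv / 2))
    p
  })
  # per-field water-holding capacity (texture differences): shifts the
  # moisture level a field settles at and, in rain-fed fields, its yield;
  # initial profile water scales with texture (porous soils store more),
  # so surface moisture is a usable proxy for a field's water supply.
  # Valley-floor irrigated fields sit on deep, fairly uniform alluvium;
  # upland rain-fed fields on thinner, more variable slope soils.
  fc_mult <- ifelse(regime == "irrigated",
                    1.05 + stats::rnorm(cfg$n_fields, 0, 0.035),
                    0.96 + stats::rnorm(cfg$n_fields, 0, 0.22))
  fsoils <- lapply(seq_len(cfg$n_fields), function(f)
    soil_profile(theta_fc = pmin(0.42, pmax(0.24, soil$theta_fc *
                                              fc_mult[f])),
                 theta_wp = soil$theta_wp))
  # the profile recharges to near capacity during the summer monsoon, so at
  # sowing every field starts essentially full; stress then develops as the
  # (texture-dependent) store is drawn down, mostly after the canopy peak
  init_thetas <- vapply(seq_len(cfg$n_fields), function(f)
    0.97 * fsoils[[f]]$theta_fc[1], numeric(1))

  dates <- weather$date
  nd <- length(dates)
  truth_lai <- matrix(NA_real_, nd, cfg$n_fields,
                      dimnames = list(as.character(dates), NULL))
  truth_sm <- truth_lai
  trajectories <- vector("list", cfg$n_fields)
  yields <- numeric(cfg$n_fields)
  min_stress <- numeric(cfg$n_fields)
  for (f in seq_len(cfg$n_fields)) {
    mg <- management(cfg$sowing_date,
                     irrigation = if (regime[f] == "irrigated")
                       cfg$irrigation
                     else cfg$irrigation[0, ])
    tr <- simulate_crop(fsoils[[f]], weather, mg, fparams[[f]],
                        init_thetas[f])
    trajectories[[f]] <- tr
    yields[f] <- attr(tr, "yield")
    min_stress[f] <- min(tr$stress[tr$stage %in% COMPOSITE_STAGES])
    idx <- match(as.character(tr$date), rownames(truth_lai))
    truth_lai[idx, f] <- tr$lai
    truth_sm[idx, f] <- tr$theta_0_20
    if (max(idx) < nd) {           # harvested: bare ground, moisture frozen
      truth_lai[(max(idx) + 1):nd, f] <- 0
      truth_sm[(max(idx) + 1):nd, f] <- tr$theta_0_20[nrow(tr)]
    }
  }

  # terrain consistent with the regime assignment: irrigated valley floor,
  # rain-fed upland; slope supplied directly
  elev <- matrix(400, cfg$grid_n, cfg$grid_n)
  slope <- matrix(3, cfg$grid_n, cfg$grid_n)
  for (f in which(regime == "rain_fed")) {
    elev[lay$ids == f] <- 750
    slope[lay$ids == f] <- 8
  }
  terrain <- terrain_grid(
    grid_raster(elev, cellsize = cfg$cellsize),
    grid_raster(slope, cellsize = cfg$cellsize))
  regime_code <- matrix(REGIME_CODES[["non_wheat"]], cfg$grid_n, cfg$grid_n)
  for (f in seq_len(cfg$n_fields))
    regime_code[lay$ids == f] <- REGIME_CODES[[regime[f]]]
  regime_mask <- same_grid(terrain$elevation, regime_code)
  class(regime_mask) <- c("regime_mask", class(regime_mask))

  sd_list <- lapply(trajectories, stage_entry_dates)
  stage_dates <- as.Date(vapply(COMPOSITE_STAGES, function(s)
    stats::median(vapply(sd_list, function(x) as.numeric(x[[s]]),
                         numeric(1)), na.rm = TRUE), numeric(1)),
    origin = "1970-01-01")
  names(stage_dates) <- COMPOSITE_STAGES

  structure(list(cfg = cfg, weather = weather,
                 fields = data.frame(field = seq_len(cfg$n_fields),
                                     regime = regime,
                                     row = lay$centers[, 1],
                                     col = lay$centers[, 2],
                                     yield = yields,
                                     min_stress = min_stress),
                 trajectories = trajectories, truth_lai = truth_lai,
                 truth_sm = truth_sm, terrain = terrain,
                 field_map = grid_raster(lay$ids + 0,
                                         cellsize = cfg$cellsize),
                 regime_mask = regime_mask, stage_dates = stage_dates,
                 soil = soil, params = base),
            class = "wheat_scenario")
}

#' @export
print.wheat_scenario <- function(x, ...) {
  cat(sprintf("wheat_scenario: %d fields (%d irrigated, %d rain-fed), %s to %s\n",
              x$cfg$n_fields, sum(x$fields$regime == "irrigated"),
              sum(x$fields$regime == "rain_fed"),
              format(x$cfg$sowing_date), format(x$cfg$season_end)))
  cat(sprintf("  seasonal rainfall %.0f mm; median yield irr %.0f / rf %.0f kg/ha\n",
              sum(x$weather$precip),
              stats::median(x$fields$yield[x$fields$regime == "irrigated"]),
              stats::median(x$fields$yield[x$fields$regime == "rain_fed"])))
  invisible(x)
}

.truth_at <- function(scn, date, what = c("lai", "sm")) {
  what <- match.arg(what)
  key <- as.character(as.Date(date))
  m <- if (what == "lai") scn$truth_lai else scn$truth_sm
  if (!key %in% rownames(m)) stop("no truth coverage at ", key)
  m[key, ]
}

# Per-pixel truth field: field pixels get the field value, background a
# constant non-wheat level.
.truth_grid <- function(scn, vals, background) {
  ids <- unclass(scn$field_map)
  out <- matrix(background, nrow(ids), ncol(ids))
  wheat <- ids > 0
  out[wheat] <- vals[ids[wheat]]
  out
}

#' Render a synthetic optical scene
#'
#' Builds red/NIR/MIR reflectances whose NDVI and NDWI sit exactly on the
#' inverse of the retrieval relations at the truth LAI (NDVI =
#' (LAI + 0.9866)/8.8049; canopy water content 0.34 + `mveg_per_lai` x LAI
#' mapped back through the NDWI polynomial), then adds Gaussian reflectance
#' noise. Background pixels render as sparse vegetation (NDVI ~ 0.15).
#' Dates listed in `cfg$cloud_masked` give a fully nodata scene.
#'
#' @param scn a [generate_truth()] scenario.
#' @param date scene date (must have truth coverage).
#' @param noise add reflectance noise (turn off for round-trip checks).
#' @return an object of class `optical_scene`: list with `date` and
#'   [grid_raster()]s `red`, `nir`, `mir`.
#' @export
render_optical <- function(scn, date, noise = TRUE) {
  cfg <- scn$cfg
  date <- as.Date(date)
  tmpl <- scn$field_map
  if (date %in% cfg$cloud_masked) {
    na <- same_grid(tmpl, NA_real_)
    return(structure(list(date = date, red = na, nir = na, mir = na),
                     class = "optical_scene"))
  }
  lai <- .truth_at(scn, date, "lai")
  mm <- 1 + cfg$render_mismatch
  ndvi_v <- (lai + 0.9866) / 8.8049 * mm
  lai_grid <- .truth_grid(scn, lai, background = NA)
  ndvi_grid <- .truth_grid(scn, ndvi_v, background = 0.15)
  S <- cfg$nir_plus_red
  nir <- S * (1 + ndvi_grid) / 2
  red <- S * (1 - ndvi_grid) / 2
  # canopy water saturates where the NDWI polynomial reaches its NDWI = 1
  # ceiling (very dense canopies)
  mveg_grid <- pmin(3.14, 0.34 + cfg$mveg_per_lai * mm *
                      .truth_grid(scn, lai, background = 0.1))
  w <- ndwi_from_mveg(mveg_grid)
  mir <- nir * (1 - w) / (1 + w)
  if (noise && cfg$refl_sd > 0) {
    set.seed((cfg$seed * 97L + as.integer(date)) %% 2147483647L)
    jitter <- function(m) pmin(1, pmax(1e-3,
      m + matrix(stats::rnorm(length(m), 0, cfg$refl_sd), nrow(m))))
    red <- jitter(red); nir <- jitter(nir); mir <- jitter(mir)
  }
  structure(list(date = date,
                 red = same_grid(tmpl, red),
                 nir = same_grid(tmpl, nir),
                 mir = same_grid(tmpl, mir)),
            class = "optical_scene")
}

#' Render a synthetic SAR scene
#'
#' Maps truth 0-20 cm soil moisture through the inverse of the linear
#' backscatter-moisture retrieval to a soil backscatter (dB), pushes it
#' through the forward water cloud model with the truth canopy water
#' content, converts to dB and adds Gaussian backscatter noise. Wetter truth
#' renders to larger soil backscatter by construction.
#'
#' @param scn a [generate_truth()] scenario.
#' @param date scene date.
#' @param noise add dB-domain noise (turn off for round-trip checks).
#' @param sm_coef slope/intercept of the moisture retrieval whose inverse
#'   drives the rendering (defaults to the standard 0.0133 / 0.3815 pair).
#' @return an object of class `sar_scene`: list with `date`, `sigma_can_db`
#'   ([grid_raster()]), `theta_inc` (degrees), `mveg_true` (the rendering
#'   canopy water content raster, for exactness checks).
#' @export
render_sar <- function(scn, date, noise = TRUE,
                       sm_coef = c(slope = 0.0133, intercept = 0.3815)) {
  cfg <- scn$cfg
  date <- as.Date(date)
  sm <- .truth_at(scn, date, "sm")
  lai <- .truth_at(scn, date, "lai")
  mm <- 1 + cfg$render_mismatch
  sm_grid <- .truth_grid(scn, sm, background = 0.20)
  sigma_soil_db <- (sm_grid - sm_coef[["intercept"]]) / sm_coef[["slope"]] * mm
  mveg_grid <- pmin(3.14, 0.34 + cfg$mveg_per_lai * mm *
                      .truth_grid(scn, lai, background = 0.1))
  sig_can <- wcm_forward(db_to_linear(sigma_soil_db), mveg_grid,
                         cfg$theta_inc)
  db <- linear_to_db(sig_can)
  if (noise && cfg$sar_sd_db > 0) {
    set.seed((cfg$seed * 131L + as.integer(date)) %% 2147483647L)
    db <- db + matrix(stats::rnorm(length(db), 0, cfg$sar_sd_db), nrow(db))
  }
  tmpl <- scn$field_map
  structure(list(date = date, sigma_can_db = same_grid(tmpl, db),
                 theta_inc = cfg$theta_inc,
                 mveg_true = same_grid(tmpl, mveg_grid)),
            class = "sar_scene")
}

#' Sample the synthetic field campaign
#'
#' One sampling site per field (the field's centre pixel): noisy LAI and
#' 0-20 cm soil moisture at the jointing and heading-filling campaign dates,
#' noisy yield at maturity, and a seeded calibration/validation split per
#' regime (default 10 calibration + 15 validation irrigated, 10 + 10
#' rain-fed).
#'
#' @param scn a [generate_truth()] scenario.
#' @param dates named campaign dates (defaults to `cfg$meas_dates`).
#' @return data.frame with one row per site: `site`, `field`, `regime`,
#'   `role` (`cal` / `val`), `row`, `col`, per-date `lai_*` and `sm_*`
#'   columns, and `yield`.
#' @export
sample_field_measurements <- function(scn, dates = NULL) {
  cfg <- scn$cfg
  if (is.null(dates)) dates <- cfg$meas_dates
  set.seed(cfg$seed + 3L)
  out <- data.frame(site = seq_len(cfg$n_fields),
                    field = seq_len(cfg$n_fields),
                    regime = scn$fields$regime,
                    row = scn$fields$row, col = scn$fields$col)
  for (i in seq_along(dates)) {
    nm <- names(dates)[i]
    lai <- .truth_at(scn, dates[i], "lai") +
      stats::rnorm(cfg$n_fields, 0, cfg$meas_lai_sd)
    sm <- .truth_at(scn, dates[i], "sm") +
      stats::rnorm(cfg$n_fields, 0, cfg$meas_sm_sd)
    out[[paste0("lai_", nm)]] <- pmax(0, lai)
    out[[paste0("sm_", nm)]] <- pmin(0.6, pmax(0.01, sm))
  }
  out$yield <- pmax(100, scn$fields$yield +
                      stats::rnorm(cfg$n_fields, 0, cfg$meas_yield_sd))
  out$role <- "val"
  for (rg in c("irrigated", "rain_fed")) {
    idx <- which(out$regime == rg)
    n_cal <- if (rg == "irrigated") cfg$n_cal_irrigated else cfg$n_cal_rain_fed
    n_cal <- min(n_cal, length(idx))
    out$role[sample(idx, n_cal)] <- "cal"
  }
  out
}
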