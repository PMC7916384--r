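# Phenophase codes used throughout: 0 presowing, 1 green-up, 2 jointing,
# 3 heading-filling, 4 milking, 5 mature.
STAGE_LEVELS <- c("presowing", "green_up", "jointing", "heading_filling",
                  "milking", "mature")
COMPOSITE_STAGES <- c("green_up", "jointing", "heading_filling", "milking")

#' Soil profile description
#'
#' Layered soil hydraulic description for the daily water balance. The default
#' seven layers (0-10, 10-20, 20-50, 50-80, 80-120, 120-160, 160-200 cm)
#' follow the standard agronomic sampling profile for deep loess soils.
#'
#' @param layer_depths layer thicknesses, cm.
#' @param theta_fc,theta_wp,theta_sat per-layer (recycled) field capacity,
#'   wilting point and saturation, cm3 cm-3.
#' @return an object of class `soil_profile`.
#' @export
soil_profile <- function(layer_depths = c(10, 10, 30, 30, 40, 40, 40),
                         theta_fc = 0.34, theta_wp = 0.10, theta_sat = 0.46) {
  L <- length(layer_depths)
  theta_fc <- rep_len(theta_fc, L)
  theta_wp <- rep_len(theta_wp, L)
  theta_sat <- rep_len(theta_sat, L)
  if (any(layer_depths <= 0)) stop("layer depths must be strictly positive")
  if (any(!(0 < theta_wp & theta_wp < theta_fc & theta_fc < theta_sat &
            theta_sat < 1)))
    stop("require 0 < theta_wp < theta_fc < theta_sat < 1 in every layer")
  structure(list(layer_depths = layer_depths, theta_fc = theta_fc,
                 theta_wp = theta_wp, theta_sat = theta_sat),
            class = "soil_profile")
}

#' Field management record
#'
#' @param sowing_date `Date` of sowing.
#' @param irrigation data.frame with columns `date`, `depth_mm` (may be empty).
#' @param fertilization data.frame with columns `date`, `amount`; carried for
#'   provenance, inert in the water-limited simulator.
#' @return an object of class `management`.
#' @export
management <- function(sowing_date,
                       irrigation = data.frame(date = as.Date(character()),
                                               depth_mm = numeric()),
                       fertilization = data.frame(date = as.Date(character()),
                                                  amount = numeric())) {
  sowing_date <- as.Date(sowing_date)
  irrigation$date <- as.Date(irrigation$date)
  if (nrow(irrigation) && any(irrigation$depth_mm < 0))
    stop("irrigation depths must be >= 0")
  structure(list(sowing_date = sowing_date, irrigation = irrigation,
                 fertilization = fertilization), class = "management")
}

#' Crop growth parameters
#'
#' Parameters of the reduced-order winter wheat simulator. Stage thresholds
#' are cumulative growing degree days (base `base_temp`) at which the crop
#' enters green-up, jointing, heading-filling, milking and maturity; defaults
#' place these stages on the mid-February to mid-June calendar of a
#' warm-temperate winter wheat season sown in mid-October, with the LAI peak
#' about 205 days after sowing.
#'
#' @param base_temp phenology base temperature, degC.
#' @param stage_gdd named increasing thresholds (degC d) for the five stages.
#' @param lai_max potential peak LAI, m2 m-2.
#' @param rgr relative LAI growth rate, d-1.
#' @param senescence_rate post-peak relative LAI decline, d-1.
#' @param rue radiation-use efficiency, g dry matter per MJ intercepted.
#' @param harvest_index grain fraction of above-ground biomass at maturity.
#' @param k_ext canopy light extinction coefficient (Beer's law).
#' @param et_coeff multiplier on radiation-based potential evapotranspiration.
#' @param lai_init LAI of the established autumn canopy carried through
#'   winter (winter wheat tillers before dormancy).
#' @return an object of class `crop_params`.
#' @export
crop_params <- function(base_temp = 0,
                        stage_gdd = c(green_up = 600, jointing = 860,
                                      heading_filling = 1050, milking = 1450,
                                      mature = 2100),
                        lai_max = 7, rgr = 0.065, senescence_rate = 0.08,
                        rue = 1.3, harvest_index = 0.45, k_ext = 0.6,
                        et_coeff = 0.9, lai_init = 0.5) {
  stopifnot(length(stage_gdd) == 5, all(diff(stage_gdd) > 0),
            all(c(lai_max, rgr, senescence_rate, rue, k_ext, et_coeff,
                  lai_init) > 0),
            harvest_index > 0, harvest_index < 1)
  names(stage_gdd) <- STAGE_LEVELS[-1]
  structure(list(base_temp = base_temp, stage_gdd = stage_gdd,
                 lai_max = lai_max, rgr = rgr,
                 senescence_rate = senescence_rate, rue = rue,
                 harvest_index = harvest_index, k_ext = k_ext,
                 et_coeff = et_coeff, lai_init = lai_init),
            class = "crop_params")
}

#' Daily thermal time
#'
#' Growing degree days accumulated on one day: mean temperature above the base
#' temperature, clamped at zero.
#'
#' @param tmax,tmin daily maximum and minimum air temperature, degC.
#' @param base_temp base temperature, degC.
#' @return thermal time, degC d (vectorised).
#' @export
thermal_time <- function(tmax, tmin, base_temp = 0) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  pmax(0, (tmax + tmin) / 2 - base_temp)
}

#' Soil water stress factor
#'
#' Linear ramp of water availability: 0 at or below wilting point, 1 at or
#' above field capacity.
#'
#' @param theta root-zone volumetric soil moisture, cm3 cm-3 (vectorised).
#' @param theta_wp,theta_fc wilting point and field capacity, cm3 cm-3.
#' @return stress factor in [0, 1].
#' @export
water_stress_factor <- function(theta, theta_wp, theta_fc) {
  if (any(theta_wp >= theta_fc))
    stop("degenerate profile: theta_wp must be < theta_fc")
  pmin(1, pmax(0, (theta - theta_wp) / (theta_fc - theta_wp)))
}

#' Root-zone mean soil moisture
#'
#' Thickness-weighted mean moisture of the layers intersecting `[0, depth]`,
#' matching the 0-20 cm depth of gravimetric field sampling.
#'
#' @param theta per-layer moisture: a vector, or a matrix with one row per
#'   ensemble member.
#' @param soil a [soil_profile()] (or a numeric vector of layer depths, cm).
#' @param depth aggregation depth from the surface, cm.
#' @return scalar (or per-row vector) mean moisture, cm3 cm-3.
#' @export
root_zone_theta <- function(theta, soil, depth = 20) {
  depths <- if (inherits(soil, "soil_profile")) soil$layer_depths else soil
  if (depth <= 0) stop("depth must be positive")
  if (depth > sum(depths) + 1e-9) stop("depth exceeds the soil profile")
  tops <- cumsum(c(0, depths[-length(depths)]))
  w <- pmax(0, pmin(tops + depths, depth) - tops)
  w <- w / sum(w)
  if (is.matrix(theta)) as.numeric(theta %*% w) else sum(theta * w)
}

# Radiation-based (Priestley-Taylor-style) potential ET, mm d-1. Uses the
# slope of the saturation vapour pressure curve at the daily mean temperature;
# net radiation taken as 75% of global radiation; latent heat 2.45 MJ kg-1.
potential_et <- function(tmean, srad) {
  s <- 4098 * 0.6108 * exp(17.27 * tmean / (tmean + 237.3)) /
    (tmean + 237.3)^2
  pmax(0, 1.26 * s / (s + 0.066) * 0.75 * srad / 2.45)
}

# Rooting depth (cm) as a function of thermal time; starts at the surface
# layers and deepens with development, capped by the profile.
root_depth_cm <- function(gdd, soil) {
  min(sum(soil$layer_depths), 20 + 0.09 * gdd)
}

stage_from_gdd <- function(gdd, stage_gdd) {
  sum(gdd >= stage_gdd)  # 0..5
}

# --- ensemble step kernel -----------------------------------------------
# ens: list(lai = n-vector, theta = n x L matrix, biomass = n-vector,
#           gdd = scalar, stage = scalar code). Weather and phenology are
# shared across members; only lai/theta/biomass differ. Returns the updated
# ensemble plus the fluxes needed for water-balance checks (all in mm).
step_ensemble <- function(ens, tmax, tmin, precip, srad, irr_mm, soil,
                          params) {
  L <- length(soil$layer_depths)
  d_mm <- soil$layer_depths * 10           # layer capacity scale, mm per unit theta
  theta <- ens$theta
  n <- nrow(theta)

  tt <- thermal_time(tmax, tmin, params$base_temp)
  gdd <- ens$gdd + tt
  stage <- stage_from_gdd(gdd, params$stage_gdd)

  storage0 <- as.numeric(theta %*% d_mm)

  # water stress over the current root zone: deep roots buffer short dry
  # spells, while assimilation updates to the surface layers still propagate
  # into the stress term (directly and through ensemble cross-covariances)
  rd <- root_depth_cm(ens$gdd, soil)
  th_rz <- root_zone_theta(theta, soil, depth = rd)
  tops0 <- cumsum(c(0, soil$layer_depths[-L]))
  wrz <- pmax(0, pmin(tops0 + soil$layer_depths, rd) - tops0)
  wrz <- wrz / sum(wrz)
  stress <- water_stress_factor(th_rz, sum(soil$theta_wp * wrz),
                                sum(soil$theta_fc * wrz))

  # infiltration into the top layer, cascade of excess above field capacity;
  # skipped on dry days with no layer above capacity (nothing can move)
  infil <- precip + irr_mm
  drain <- numeric(n)
  if (infil > 0 ||
      any(theta > matrix(soil$theta_fc, n, L, byrow = TRUE))) {
    inflow <- rep(infil, n)
    for (l in seq_len(L)) {
      theta[, l] <- theta[, l] + inflow / d_mm[l]
      excess <- pmax(0, theta[, l] - soil$theta_fc[l]) * d_mm[l]
      theta[, l] <- pmin(theta[, l], soil$theta_fc[l])
      inflow <- excess
    }
    drain <- inflow
  }

  # transpiration + evaporation, partitioned over the rooted layers by
  # thickness; extraction limited by water above wilting point. A canopy
  # cover factor keeps dormant-season ET low: soil evaporation under sparse
  # cover is supply-limited, transpiration scales with intercepted light.
  pet <- potential_et((tmax + tmin) / 2, srad)
  cover <- 0.35 + 0.65 * (1 - exp(-params$k_ext * ens$lai))
  demand <- params$et_coeff * stress * cover * pet  # per member, mm
  w <- wrz
  aet <- numeric(n)
  for (l in seq_len(L)) {
    if (w[l] == 0) next
    want <- demand * w[l]
    avail <- pmax(0, theta[, l] - soil$theta_wp[l]) * d_mm[l]
    take <- pmin(want, avail)
    theta[, l] <- theta[, l] - take / d_mm[l]
    aet <- aet + take
  }

  # canopy dynamics: logistic growth from green-up until milking, then
  # exponential senescence; standstill before green-up and after maturity
  lai <- ens$lai
  if (stage >= 1 && stage <= 3) {
    lai <- lai + params$rgr * stress * lai * (1 - lai / params$lai_max)
  } else if (stage >= 4) {
    lai <- lai - params$senescence_rate * lai
  }
  lai <- pmax(0, lai)

  biomass <- ens$biomass
  if (stage >= 1 && stage < 5) {
    biomass <- biomass +
      params$rue * srad * (1 - exp(-params$k_ext * lai)) * stress * 10
  }

  storage1 <- as.numeric(theta %*% d_mm)
  list(lai = lai, theta = theta, biomass = biomass, gdd = gdd, stage = stage,
       flux = list(infil = infil, aet = aet, drain = drain,
                   dstorage = storage1 - storage0, stress = stress))
}

#' One daily step of the crop model
#'
#' Advances a single crop state by one day: thermal time and phenophase,
#' logistic LAI growth under water stress (senescence after the milking
#' stage), a cascading-bucket layered water balance with radiation-based
#' potential ET, and light-interception biomass accumulation.
#'
#' @param state list with `lai`, `theta` (per-layer, cm3 cm-3), `biomass`
#'   (kg ha-1), `gdd` (degC d), `stage` (code or name), `day` (days after
#'   sowing).
#' @param wx one-row weather data.frame (`date`, `tmax`, `tmin`, `precip`,
#'   `srad`).
#' @param soil a [soil_profile()].
#' @param mgmt a [management()]; irrigation falling on `wx$date` is applied.
#' @param params a [crop_params()].
#' @return the updated state; fluxes of the day are attached as
#'   `attr(, "flux")` (mm): infiltration, actual ET, bottom drainage, storage
#'   change, and the day's stress factor.
#' @export
step_crop <- function(state, wx, soil, mgmt, params) {
  irr <- 0
  if (nrow(mgmt$irrigation))
    irr <- sum(mgmt$irrigation$depth_mm[mgmt$irrigation$date == wx$date])
  ens <- list(lai = state$lai, theta = matrix(state$theta, nrow = 1),
              biomass = state$biomass, gdd = state$gdd,
              stage = if (is.character(state$stage))
                match(state$stage, STAGE_LEVELS) - 1 else state$stage)
  out <- step_ensemble(ens, wx$tmax, wx$tmin, wx$precip, wx$srad, irr,
                       soil, params)
  res <- list(day = state$day + 1, lai = out$lai, theta = as.numeric(out$theta),
              biomass = out$biomass, gdd = out$gdd, stage = out$stage)
  attr(res, "flux") <- lapply(out$flux, as.numeric)
  res
}

validate_weather <- function(wx) {
  need <- c("date", "tmax", "tmin", "precip", "srad")
  if (!all(need %in% names(wx)))
    stop("weather table must have columns ", paste(need, collapse = ", "))
  wx$date <- as.Date(wx$date)
  if (any(wx$tmax < wx$tmin)) stop("weather has tmax < tmin")
  if (any(wx$precip < 0) || any(wx$srad < 0))
    stop("weather has negative precip or srad")
  wx[order(wx$date), , drop = FALSE]
}

#' Simulate a winter wheat season
#'
#' Runs the daily crop model from sowing until maturity (or the end of the
#' weather record), returning the daily trajectory of LAI, layered soil
#' moisture, thermal time, phenophase and biomass, and the final grain yield
#' (`harvest_index` x biomass at maturity). Deterministic in its inputs.
#'
#' @param soil a [soil_profile()].
#' @param wx daily weather data.frame covering sowing to maturity with no
#'   gaps (columns `date`, `tmax`, `tmin`, `precip`, `srad`).
#' @param mgmt a [management()].
#' @param params a [crop_params()].
#' @param init_theta initial per-layer soil moisture, cm3 cm-3 (recycled).
#' @return an object of class `crop_trajectory`: a data.frame with one row
#'   per day (`date`, `day`, `lai`, `theta_0_20`, `gdd`, `stage`, `biomass`,
#'   `stress`, per-layer `theta.*` columns) with attributes `yield` (kg ha-1),
#'   `maturity_date`, `soil`, `params`.
#' @export
simulate_crop <- function(soil, wx, mgmt, params = crop_params(),
                          init_theta = 0.33) {
  wx <- validate_weather(wx)
  wx <- wx[wx$date >= mgmt$sowing_date, , drop = FALSE]
  if (!nrow(wx) || wx$date[1] != mgmt$sowing_date)
    stop("weather does not cover the sowing date ", mgmt$sowing_date)
  gaps <- which(diff(wx$date) != 1)
  if (length(gaps))
    stop("weather gap: missing date ", wx$date[gaps[1]] + 1)

  L <- length(soil$layer_depths)
  theta0 <- pmin(rep_len(init_theta, L), soil$theta_sat)
  state <- list(day = 0, lai = params$lai_init, theta = theta0, biomass = 0,
                gdd = 0, stage = 0)
  n <- nrow(wx)
  rec <- data.frame(date = wx$date, day = seq_len(n),
                    lai = NA_real_, theta_0_20 = NA_real_, gdd = NA_real_,
                    stage = NA_character_, biomass = NA_real_,
                    stress = NA_real_)
  th_mat <- matrix(NA_real_, n, L,
                   dimnames = list(NULL, paste0("theta.", seq_len(L))))
  maturity <- NA
  for (i in seq_len(n)) {
    state <- step_crop(state, wx[i, ], soil, mgmt, params)
    fl <- attr(state, "flux")
    rec$lai[i] <- state$lai
    rec$theta_0_20[i] <- root_zone_theta(state$theta, soil, 20)
    rec$gdd[i] <- state$gdd
    rec$stage[i] <- STAGE_LEVELS[state$stage + 1]
    rec$biomass[i] <- state$biomass
    rec$stress[i] <- fl$stress
    th_mat[i, ] <- state$theta
    if (state$stage >= 5) { maturity <- i; break }
  }
  if (is.na(maturity)) maturity <- n
  rec <- cbind(rec[seq_len(maturity), , drop = FALSE],
               th_mat[seq_len(maturity), , drop = FALSE])
  yield <- max(0, params$harvest_index * rec$biomass[maturity])
  structure(rec, yield = yield, maturity_date = rec$date[maturity],
            soil = soil, params = params, sowing_date = mgmt$sowing_date,
            class = c("crop_trajectory", "data.frame"))
}

#' Final yield of a simulated trajectory
#' @param x a `crop_trajectory`.
#' @return grain yield, kg ha-1.
#' @export
trajectory_yield <- function(x) attr(x, "yield")

#' @export
print.crop_trajectory <- function(x, ...) {
  if (!all(c("lai", "stage", "date") %in% names(x)))
    return(print.data.frame(x, ...))
  cat(sprintf(
    "crop_trajectory: %d days from %s; peak LAI %.2f; yield %.0f kg/ha\n",
    nrow(x), format(attr(x, "sowing_date")), max(x$lai), attr(x, "yield")))
  st <- x$stage[!duplicated(x$stage)]
  on <- x$date[!duplicated(x$stage)]
  cat("  stage entry:", paste(sprintf("%s %s", st, format(on)),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.crop_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$date, x$lai, type = "l", xlab = "date", ylab = "LAI (m2/m2)", ...)
  plot(x$date, x$theta_0_20, type = "l", xlab = "date",
       ylab = "theta 0-20 cm (cm3/cm3)", ...)
  invisible(x)
}

# First calendar date on which the trajectory is in each composite stage;
# used to anchor scene-date selection per phenophase.
stage_entry_dates <- function(traj) {
  out <- lapply(COMPOSITE_STAGES, function(s) {
    d <- traj$date[traj$stage == s]
    if (!length(d)) return(as.Date(NA))
    d[1] + floor(length(d) / 2)   # stage midpoint
  })
  stats::setNames(do.call(c, out), COMPOSITE_STAGES)
}
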