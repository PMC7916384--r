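#' Assimilation configuration
#'
#' Ensemble size, error magnitudes and strategy for the ensemble Kalman
#' filter. The default relative standard deviations are the calibrated
#' model/observation error levels for this system: 17% (simulated LAI), 9%
#' (simulated soil moisture), 13% (retrieved LAI), 8% (retrieved soil
#' moisture).
#'
#' @param n_ensemble number of ensemble members (`>= 2`).
#' @param sd_model_lai,sd_model_sm relative SD of the model forecast for LAI
#'   and soil moisture.
#' @param sd_obs_lai,sd_obs_sm relative SD of the retrieved observations.
#' @param strategy which observation kinds are assimilated: `"LAI_only"`,
#'   `"SM_only"` or `"joint"`.
#' @param seed RNG seed; every random draw in an assimilation run flows from
#'   it.
#' @param obs_sd_floor minimum absolute observation SD, same units as the
#'   observation (guards against zero-variance observations at tiny values).
#' @return an object of class `assim_config`.
#' @export
assim_config <- function(n_ensemble = 100,
                         sd_model_lai = 0.17, sd_model_sm = 0.09,
                         sd_obs_lai = 0.13, sd_obs_sm = 0.08,
                         strategy = c("joint", "LAI_only", "SM_only"),
                         seed = 1L, obs_sd_floor = 0.01) {
  strategy <- match.arg(strategy)
  stopifnot(n_ensemble >= 2,
            all(c(sd_model_lai, sd_model_sm, sd_obs_lai, sd_obs_sm) > 0))
  structure(list(n_ensemble = as.integer(n_ensemble),
                 sd_model_lai = sd_model_lai, sd_model_sm = sd_model_sm,
                 sd_obs_lai = sd_obs_lai, sd_obs_sm = sd_obs_sm,
                 strategy = strategy, seed = as.integer(seed),
                 obs_sd_floor = obs_sd_floor),
            class = "assim_config")
}

#' Observation table constructor
#'
#' @param date observation dates.
#' @param kind `"LAI"` or `"SM"` per row.
#' @param value retrieved value (m2 m-2 or cm3 cm-3, `>= 0`).
#' @param sd observation error SD in the same units; `NA` means derive it
#'   from the configured relative SD at assimilation time.
#' @return a data.frame of class `obs_table`.
#' @export
obs_table <- function(date, kind, value, sd = NA_real_) {
  kind <- as.character(kind)
  if (!all(kind %in% c("LAI", "SM"))) stop("kind must be 'LAI' or 'SM'")
  if (any(value < 0)) stop("observed values must be >= 0")
  out <- data.frame(date = as.Date(date), kind = kind, value = value,
                    sd = rep_len(as.numeric(sd), length(value)))
  class(out) <- c("obs_table", "data.frame")
  out
}

# Multiplicative lognormal-free Gaussian perturbation x * (1 + eps),
# eps ~ N(0, sd^2), clamped to physical bounds.
.perturb <- function(x, sd, lo = 0, hi = Inf) {
  if (is.matrix(x)) {
    e <- matrix(stats::rnorm(length(x), 0, sd), nrow(x), ncol(x))
  } else {
    e <- stats::rnorm(length(x), 0, sd)
  }
  pmin(hi, pmax(lo, x * (1 + e)))
}

#' Monte Carlo ensemble generation around a crop state
#'
#' Perturbs LAI and per-layer soil moisture multiplicatively with independent
#' Gaussian relative errors, producing the forecast ensemble the filter
#' works on. Clamped to physical bounds (LAI `>= 0`, moisture within
#' `[0, theta_sat]`).
#'
#' @param state list with `lai` (scalar) and `theta` (per-layer vector);
#'   optional `biomass`, `gdd`, `stage` are replicated unchanged.
#' @param soil a [soil_profile()] (supplies the moisture bounds).
#' @param cfg an [assim_config()]; `sd_model_lai` / `sd_model_sm` are used.
#' @param n ensemble size (defaults to `cfg$n_ensemble`).
#' @param seed optional seed; when given, the draw is reproducible on its own.
#' @return an ensemble: list with `lai` (n-vector), `theta` (n x L matrix),
#'   `biomass`, `gdd`, `stage`.
#' @export
perturb_ensemble <- function(state, soil, cfg, n = cfg$n_ensemble,
                             seed = NULL) {
  if (n < 2) stop("ensemble size must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  L <- length(soil$layer_depths)
  theta0 <- matrix(rep(state$theta, each = n), nrow = n)
  list(lai = .perturb(rep(state$lai, n), cfg$sd_model_lai),
       theta = .perturb(theta0, cfg$sd_model_sm,
                        hi = matrix(rep(soil$theta_sat, each = n), nrow = n)),
       biomass = rep(if (is.null(state$biomass)) 0 else state$biomass, n),
       gdd = if (is.null(state$gdd)) 0 else state$gdd,
       stage = if (is.null(state$stage)) 0 else state$stage)
}

#' Ensemble Kalman filter analysis step
#'
#' Stochastic (perturbed-observation) EnKF update
#' `Xa = Xf + K (D - H Xf)`, with gain
#' `K = P H' (H P H' + R)^-1` where `P` is the ensemble sample covariance.
#' Each member sees its own observation draw `N(value, sd^2)`; setting
#' `perturb_obs = FALSE` gives the deterministic unperturbed-observation
#' variant (useful for hand-checkable algebra, but it understates analysis
#' spread and is not used in production runs).
#'
#' @param X forecast ensemble matrix, members in rows, state components in
#'   columns.
#' @param y observation vector (length m).
#' @param sd observation error SDs (length m, `> 0`).
#' @param H m x d observation operator.
#' @param perturb_obs draw per-member observation perturbations.
#' @return the analysis ensemble matrix, same shape as `X`.
#' @export
enkf_update <- function(X, y, sd, H, perturb_obs = TRUE) {
  X <- as.matrix(X)
  H <- matrix(H, ncol = ncol(X))
  m <- length(y)
  stopifnot(nrow(H) == m, length(sd) == m, all(sd > 0))
  n <- nrow(X)
  P <- stats::cov(X)
  R <- diag(sd^2, m)
  S <- H %*% P %*% t(H) + R
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv)) {
    message("enkf_update: singular innovation covariance; regularizing R")
    Sinv <- solve(S + diag(1e-8 * max(1, diag(S)), m))
  }
  K <- P %*% t(H) %*% Sinv
  D <- matrix(y, n, m, byrow = TRUE)
  if (perturb_obs)
    D <- D + matrix(stats::rnorm(n * m), n, m) %*% diag(sd, m)
  X + (D - X %*% t(H)) %*% t(K)
}

# Observation operator rows for the (lai, theta_1..theta_L) state vector.
obs_operator <- function(kinds, soil) {
  L <- length(soil$layer_depths)
  tops <- cumsum(c(0, soil$layer_depths[-L]))
  w20 <- pmax(0, pmin(tops + soil$layer_depths, 20) - tops)
  w20 <- w20 / sum(w20)
  rows <- lapply(kinds, function(k) {
    if (k == "LAI") c(1, rep(0, L)) else c(0, w20)
  })
  do.call(rbind, rows)
}

filter_obs_by_strategy <- function(obs, strategy) {
  keep <- switch(strategy,
                 LAI_only = obs$kind == "LAI",
                 SM_only = obs$kind == "SM",
                 joint = rep(TRUE, nrow(obs)))
  obs[keep, , drop = FALSE]
}

#' Run an EnKF-assimilated crop simulation
#'
#' Propagates every ensemble member through the daily crop model; on each
#' observation date the forecast ensemble is refreshed with the configured
#' multiplicative model-error perturbation (LAI 17%, soil moisture 9% by
#' default) and updated against the retrieved observations (perturbed with
#' their own error SDs). The joint strategy stacks LAI and 0-20 cm moisture
#' into one observation vector so ensemble cross-covariances couple the
#' canopy and water updates; the single-variable strategies drop the other
#' kind. Analysis states are clamped to physical bounds (LAI in
#' `[0, 1.5 lai_max]` - the model's nominal canopy cap plus headroom, so
#' observations can correct an under-parameterized canopy - and moisture in
#' `[0, theta_sat]`), with clamp events counted.
#'
#' @param soil a [soil_profile()].
#' @param wx daily weather table covering the season.
#' @param mgmt a [management()].
#' @param params a [crop_params()].
#' @param obs an [obs_table()] of dated retrieved LAI / soil moisture values.
#' @param cfg an [assim_config()].
#' @param init_theta initial per-layer moisture, cm3 cm-3.
#' @param open_loop optional pre-computed open-loop [simulate_crop()]
#'   trajectory for these exact inputs (saves recomputation when several
#'   strategies share one baseline).
#' @return an object of class `assim_run`: daily data.frame (`date`, `day`,
#'   `lai`, `sm` = assimilated ensemble means, `lai_sd`, `sm_sd`,
#'   `lai_open`, `sm_open` = open-loop run, `stage`) with attributes
#'   `yield_members`, `yield` (ensemble-mean assimilated yield),
#'   `yield_open`, `n_updates`, `n_clamped`, `config`, `open_loop`
#'   (the open-loop `crop_trajectory`).
#' @export
assimilate <- function(soil, wx, mgmt, params, obs, cfg = assim_config(),
                       init_theta = 0.33, open_loop = NULL) {
  wx <- validate_weather(wx)
  obs <- filter_obs_by_strategy(obs, cfg$strategy)
  if (!nrow(obs))
    warning("no observations after strategy filtering; ",
            "result is the open-loop ensemble mean")
  open <- if (is.null(open_loop)) {
    simulate_crop(soil, wx, mgmt, params, init_theta)
  } else open_loop
  season <- wx[wx$date >= mgmt$sowing_date &
                 wx$date <= attr(open, "maturity_date"), , drop = FALSE]
  if (nrow(obs) && (any(obs$date < season$date[1]) ||
                    any(obs$date > wx$date[nrow(wx)])))
    stop("observations fall outside the simulated season")
  # a matured crop accepts no further updates
  obs <- obs[obs$date <= season$date[nrow(season)], , drop = FALSE]

  set.seed(cfg$seed)
  n <- cfg$n_ensemble
  L <- length(soil$layer_depths)
  theta0 <- pmin(rep_len(init_theta, L), soil$theta_sat)
  ens <- list(lai = rep(params$lai_init, n),
              theta = matrix(theta0, n, L, byrow = TRUE),
              biomass = rep(0, n), gdd = 0, stage = 0)
  irr_by_date <- numeric(0)
  if (nrow(mgmt$irrigation))
    irr_by_date <- tapply(mgmt$irrigation$depth_mm,
                          as.character(mgmt$irrigation$date), sum)

  nd <- nrow(season)
  # plain vectors in the hot loop; assembled into a data.frame afterwards
  v_lai <- v_sm <- v_lai_sd <- v_sm_sd <- numeric(nd)
  v_stage <- character(nd)
  irr_vec <- numeric(nd)
  hit <- match(names(irr_by_date), as.character(season$date))
  irr_vec[hit[!is.na(hit)]] <- irr_by_date[!is.na(hit)]
  obs_days <- match(as.character(obs$date), as.character(season$date))
  n_updates <- 0L
  n_clamped <- 0L
  for (i in seq_len(nd)) {
    st <- step_ensemble(ens, season$tmax[i], season$tmin[i],
                        season$precip[i], season$srad[i], irr_vec[i], soil,
                        params)
    ens <- st[c("lai", "theta", "biomass", "gdd", "stage")]

    hits <- !is.na(obs_days) & obs_days == i
    if (any(hits)) {
      today <- obs[hits, , drop = FALSE]
      # refresh forecast spread with the model-error perturbation
      lai_hi <- 1.5 * params$lai_max   # headroom above the nominal canopy
      ens$lai <- .perturb(ens$lai, cfg$sd_model_lai, hi = lai_hi)
      ens$theta <- .perturb(ens$theta, cfg$sd_model_sm,
                            hi = matrix(rep(soil$theta_sat, each = n),
                                        nrow = n))
      sdv <- ifelse(is.finite(today$sd), today$sd,
                    pmax(cfg$obs_sd_floor,
                         ifelse(today$kind == "LAI", cfg$sd_obs_lai,
                                cfg$sd_obs_sm) * today$value))
      H <- obs_operator(today$kind, soil)
      X <- cbind(ens$lai, ens$theta)
      Xa <- enkf_update(X, today$value, sdv, H)
      lo <- c(0, rep(0, L))
      hi <- c(lai_hi, soil$theta_sat)
      clamped <- sweep(Xa, 2, lo, "<") | sweep(Xa, 2, hi, ">")
      n_clamped <- n_clamped + sum(clamped)
      Xa <- pmax(sweep(Xa, 2, hi, pmin), matrix(lo, n, L + 1, byrow = TRUE))
      ens$lai <- Xa[, 1]
      ens$theta <- Xa[, -1, drop = FALSE]
      n_updates <- n_updates + 1L
    }

    sm_members <- root_zone_theta(ens$theta, soil, 20)
    v_lai[i] <- mean(ens$lai)
    v_sm[i] <- mean(sm_members)
    v_lai_sd[i] <- stats::sd(ens$lai)
    v_sm_sd[i] <- stats::sd(sm_members)
    v_stage[i] <- STAGE_LEVELS[ens$stage + 1]
  }
  yields <- pmax(0, params$harvest_index * ens$biomass)
  out <- data.frame(date = season$date, day = seq_len(nd), lai = v_lai,
                    sm = v_sm, lai_sd = v_lai_sd, sm_sd = v_sm_sd,
                    stage = v_stage, lai_open = open$lai[seq_len(nd)],
                    sm_open = open$theta_0_20[seq_len(nd)])
  structure(out, yield_members = yields, yield = mean(yields),
            yield_open = attr(open, "yield"), n_updates = n_updates,
            n_clamped = n_clamped, config = cfg, open_loop = open,
            class = c("assim_run", "data.frame"))
}

#' @export
print.assim_run <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "assim_run (%s, %d members): %d updates over %d days\n",
    cfg$strategy, cfg$n_ensemble, attr(x, "n_updates"), nrow(x)))
  cat(sprintf("  assimilated yield %.0f kg/ha (open loop %.0f)\n",
              attr(x, "yield"), attr(x, "yield_open")))
  invisible(x)
}

#' @export
summary.assim_run <- function(object, ...) {
  out <- list(strategy = attr(object, "config")$strategy,
              yield = attr(object, "yield"),
              yield_open = attr(object, "yield_open"),
              yield_sd = stats::sd(attr(object, "yield_members")),
              n_updates = attr(object, "n_updates"),
              n_clamped = attr(object, "n_clamped"),
              peak_lai = max(object$lai),
              peak_lai_open = max(object$lai_open))
  class(out) <- "summary.assim_run"
  out
}

#' @export
print.summary.assim_run <- function(x, ...) {
  cat(sprintf("EnKF run, strategy %s: %d updates, %d clamp events\n",
              x$strategy, x$n_updates, x$n_clamped))
  cat(sprintf("  peak LAI %.2f (open loop %.2f)\n", x$peak_lai,
              x$peak_lai_open))
  cat(sprintf("  yield %.0f +/- %.0f kg/ha (open loop %.0f)\n",
              x$yield, x$yield_sd, x$yield_open))
  invisible(x)
}

#' @export
plot.assim_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$date, x$lai_open, type = "l", lty = 2, xlab = "date",
       ylab = "LAI (m2/m2)",
       ylim = range(c(x$lai, x$lai_open), na.rm = TRUE), ...)
  graphics::lines(x$date, x$lai, col = "forestgreen")
  graphics::legend("topleft", c("assimilated", "open loop"),
                   col = c("forestgreen", "black"), lty = c(1, 2), bty = "n")
  plot(x$date, x$sm_open, type = "l", lty = 2, xlab = "date",
       ylab = "theta 0-20 cm",
       ylim = range(c(x$sm, x$sm_open), na.rm = TRUE), ...)
  graphics::lines(x$date, x$sm, col = "steelblue")
  invisible(x)
}
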