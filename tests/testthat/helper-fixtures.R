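# Small shared fixtures, built in code at load time.

# Ten days of mild spring weather with one rain event.
tiny_weather <- function(start = "2019-04-01", n = 10, precip_day = 4,
                         precip_mm = 12) {
  wx <- data.frame(date = seq(as.Date(start), by = "day", length.out = n),
                   tmax = 18, tmin = 8, precip = 0, srad = 16)
  if (!is.na(precip_day)) wx$precip[precip_day] <- precip_mm
  wx
}

# A full synthetic season of weather from the generator at a fixed seed.
season_weather <- function(seed = 42) generate_weather(scenario_config(seed))

# Two-layer toy soil: exact arithmetic is easy to follow by hand.
toy_soil <- function() soil_profile(layer_depths = c(10, 10),
                                    theta_fc = 0.30, theta_wp = 0.10,
                                    theta_sat = 0.45)

# Small scenario for pipeline-level tests: fewer fields, coarser grid.
small_scenario_cfg <- function(seed = 7)
  scenario_config(seed = seed, n_fields = 12, frac_irrigated = 0.5,
                  grid_n = 24)

small_pipeline_cfg <- function(seed = 7)
  pipeline_config(seed = seed,
                  scenario = list(n_fields = 12, frac_irrigated = 0.5,
                                  grid_n = 24, n_cal_irrigated = 4,
                                  n_cal_rain_fed = 4),
                  assimilation = list(n_ensemble = 40))

# Brute-force ordinary least squares through the normal equations,
# independent of lm().
ols_oracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  solve(t(X1) %*% X1, t(X1) %*% y)[, 1]
}

# Textbook scalar Kalman filter update (oracle for the EnKF).
kalman_oracle <- function(mu, P, y, R) {
  K <- P / (P + R)
  c(mean = mu + K * (y - mu), var = (1 - K) * P)
}
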