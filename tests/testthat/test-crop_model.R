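test_that("thermal time is the clamped mean-temperature excess", {
  expect_equal(thermal_time(10, 2, 0), 6)
  expect_equal(thermal_time(2, -6, 0), 0)
  expect_equal(thermal_time(20, 10, 4), 11)
  expect_error(thermal_time(5, 7), "tmax")
})

test_that("water stress ramps linearly from wilting point to field capacity", {
  expect_equal(water_stress_factor(0.30, 0.10, 0.30), 1)
  expect_equal(water_stress_factor(0.10, 0.10, 0.30), 0)
  expect_equal(water_stress_factor(0.20, 0.10, 0.30), 0.5)
  expect_equal(water_stress_factor(0.05, 0.10, 0.30), 0)
  expect_equal(water_stress_factor(0.40, 0.10, 0.30), 1)
  expect_error(water_stress_factor(0.2, 0.3, 0.3), "degenerate")
})

test_that("root-zone moisture is the thickness-weighted layer mean", {
  expect_equal(root_zone_theta(rep(0.25, 7), soil_profile(), 20), 0.25)
  expect_equal(root_zone_theta(c(0.2, 0.3), c(10, 10), 20), 0.25)
  # (10 x 0.2 + 10 x 0.3) / 20: only 10 cm of the lower layer counts
  expect_equal(root_zone_theta(c(0.2, 0.3), c(10, 40), 20), 0.25)
  m <- rbind(c(0.2, 0.3), c(0.4, 0.2))
  expect_equal(root_zone_theta(m, c(10, 10), 20), c(0.25, 0.30))
  expect_error(root_zone_theta(c(0.2, 0.3), c(10, 10), 0), "positive")
  expect_error(root_zone_theta(c(0.2, 0.3), c(10, 10), 50), "profile")
})

test_that("a fully stressed dry step leaves canopy and soil unchanged", {
  soil <- toy_soil()
  state <- list(day = 0, lai = 1, theta = rep(0.10, 2), biomass = 100,
                gdd = 700, stage = 2)
  mgmt <- management("2019-04-01")
  out <- step_crop(state, tiny_weather(n = 1, precip_day = NA)[1, ],
                   soil, mgmt, crop_params())
  expect_equal(out$lai, 1)
  expect_equal(out$theta, rep(0.10, 2))
  fl <- attr(out, "flux")
  expect_equal(fl$stress, 0)
  expect_equal(fl$aet, 0)
  expect_equal(fl$drain, 0)
})

test_that("each daily step conserves water to 1e-9 mm", {
  soil <- soil_profile()
  mgmt <- management("2018-10-10",
                     irrigation = data.frame(date = as.Date("2018-10-20"),
                                             depth_mm = 50))
  wx <- season_weather()
  state <- list(day = 0, lai = 0.5, theta = rep(0.28, 7), biomass = 0,
                gdd = 0, stage = 0)
  for (i in seq_len(150)) {
    state <- step_crop(state, wx[i, ], soil, mgmt, crop_params())
    fl <- attr(state, "flux")
    expect_lt(abs(fl$dstorage - (fl$infil - fl$aet - fl$drain)), 1e-9)
  }
})

test_that("well-watered LAI grows monotonically before the peak", {
  soil <- soil_profile()
  wx <- tiny_weather(start = "2019-04-01", n = 30, precip_day = NA)
  wx$precip <- 8   # abundant water every day
  mgmt <- management("2019-04-01")
  state <- list(day = 0, lai = 0.5, theta = rep(0.33, 7), biomass = 0,
                gdd = 700, stage = 2)
  lai <- numeric(30)
  for (i in 1:30) {
    state <- step_crop(state, wx[i, ], soil, mgmt, crop_params())
    lai[i] <- state$lai
  }
  expect_true(all(diff(c(0.5, lai)) > 0))
  expect_true(all(lai <= crop_params()$lai_max * (1 + 1e-9)))
})

test_that("simulation is deterministic and responds to irrigation", {
  soil <- soil_profile()
  wx <- season_weather()
  irr <- data.frame(date = as.Date(c("2019-03-10", "2019-04-12")),
                    depth_mm = c(60, 60))
  mgmt_irr <- management("2018-10-10", irrigation = irr)
  mgmt_dry <- management("2018-10-10")
  a <- simulate_crop(soil, wx, mgmt_irr, crop_params(), 0.30)
  b <- simulate_crop(soil, wx, mgmt_irr, crop_params(), 0.30)
  d <- simulate_crop(soil, wx, mgmt_dry, crop_params(), 0.30)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "yield"), attr(b, "yield"))
  expect_gte(attr(a, "yield"), attr(d, "yield"))
})

test_that("a zero-radiation season produces no biomass and no yield", {
  soil <- soil_profile()
  wx <- season_weather()
  wx$srad <- 0
  tr <- simulate_crop(soil, wx, management("2018-10-10"), crop_params(), 0.33)
  expect_equal(max(tr$biomass), 0)
  expect_equal(attr(tr, "yield"), 0)
})

test_that("weather gaps are rejected with the missing date named", {
  wx <- season_weather()
  gap_date <- wx$date[100]
  wx <- wx[-100, ]
  expect_error(simulate_crop(soil_profile(), wx, management("2018-10-10"),
                             crop_params(), 0.33),
               as.character(gap_date))
})

test_that("thermal time and phenophase advance monotonically through the season", {
  tr <- simulate_crop(soil_profile(), season_weather(),
                      management("2018-10-10"), crop_params(), 0.33)
  expect_true(all(diff(tr$gdd) >= 0))
  codes <- match(tr$stage, c("presowing", "green_up", "jointing",
                             "heading_filling", "milking", "mature"))
  expect_true(all(diff(codes) >= 0))
  # transitions happen exactly at the configured thresholds
  p <- crop_params()
  expect_equal(codes - 1,
               vapply(tr$gdd, function(g) sum(g >= p$stage_gdd), numeric(1)))
})

test_that("pointwise-wetter initial soil never lowers final yield", {
  soil <- soil_profile()
  wx <- season_weather()
  mgmt <- management("2018-10-10")
  y <- vapply(c(0.20, 0.24, 0.28, 0.32), function(th)
    attr(simulate_crop(soil, wx, mgmt, crop_params(), th), "yield"),
    numeric(1))
  expect_true(all(diff(y) >= 0))
})

test_that("degenerate soil profiles are rejected", {
  expect_error(soil_profile(theta_fc = 0.1, theta_wp = 0.2), "theta_wp")
  expect_error(soil_profile(layer_depths = c(10, -5)), "positive")
})
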