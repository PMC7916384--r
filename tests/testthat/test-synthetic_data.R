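test_that("weather generation is seeded and hits its rainfall statistics", {
  cfg <- scenario_config(seed = 5)
  w1 <- generate_weather(cfg)
  w2 <- generate_weather(cfg)
  expect_identical(w1, w2)
  expect_true(all(w1$tmax >= w1$tmin))
  expect_true(all(w1$precip >= 0) && all(w1$srad >= 0))
  # zero event rate -> bone dry
  dry <- generate_weather(scenario_config(seed = 5, rain_rate = 0))
  expect_equal(sum(dry$precip), 0)
  # mean seasonal total over replicates near rate * depth * n_days
  totals <- vapply(1:10, function(s)
    sum(generate_weather(scenario_config(seed = s))$precip), numeric(1))
  target <- cfg$rain_rate * cfg$rain_mean *
    as.numeric(cfg$season_end - cfg$sowing_date + 1)
  expect_lt(abs(mean(totals) - target) / target, 0.2)
})

test_that("scenario truth is deterministic and regime assignment is honoured", {
  cfg <- small_scenario_cfg(seed = 3)
  s1 <- generate_truth(cfg)
  s2 <- generate_truth(cfg)
  expect_identical(s1$fields, s2$fields)
  expect_identical(s1$truth_lai, s2$truth_lai)
  expect_equal(sum(s1$fields$regime == "irrigated"),
               round(cfg$frac_irrigated * cfg$n_fields))
  all_irr <- generate_truth(scenario_config(seed = 3, n_fields = 6,
                                            frac_irrigated = 1,
                                            grid_n = 24))
  expect_true(all(all_irr$fields$regime == "irrigated"))
})

test_that("terrain thresholds recover the configured regime mix", {
  scn <- generate_truth(small_scenario_cfg(seed = 4))
  # classify from the generated terrain alone, with truth field footprints
  wheat <- wheatDA:::same_grid(scn$field_map,
                               as.numeric(unclass(scn$field_map) > 0))
  rm <- regime_split(wheat, scn$terrain)
  expect_equal(unclass(rm), unclass(scn$regime_mask))
})

test_that("rain-fed truths are stressed while irrigated truths are not", {
  for (seed in c(2, 9)) {
    scn <- generate_truth(scenario_config(seed = seed))
    f <- scn$fields
    expect_true(all(f$min_stress[f$regime == "rain_fed"] < 1))
    expect_true(all(f$min_stress[f$regime == "irrigated"] >= 0.8))
    expect_lt(median(f$yield[f$regime == "rain_fed"]),
              median(f$yield[f$regime == "irrigated"]))
  }
})

test_that("noise-free optical rendering inverts exactly to truth LAI", {
  scn <- generate_truth(small_scenario_cfg(seed = 6))
  d <- as.Date("2019-04-16")
  sc <- render_optical(scn, d, noise = FALSE)
  lai_grid <- apply_retrieval(retrieval_model(8.8049, -0.9866, "LAI"),
                              ndvi(sc$red, sc$nir))
  ids <- unclass(scn$field_map)
  truth <- wheatDA:::.truth_at(scn, d, "lai")
  for (f in c(1, 5, 12)) {
    px <- which(ids == f)[1]
    expect_equal(unclass(lai_grid)[px], truth[f], tolerance = 1e-6)
  }
  # canopy water also round-trips through the NDWI polynomial
  mv <- mveg_from_ndwi(ndwi(sc$nir, sc$mir))
  px <- which(ids == 3)[1]
  expect_equal(unclass(mv)[px], 0.34 + scn$cfg$mveg_per_lai * truth[3],
               tolerance = 1e-6)
})

test_that("noise-free SAR rendering inverts exactly to truth soil moisture", {
  scn <- generate_truth(small_scenario_cfg(seed = 6))
  d <- as.Date("2019-04-19")
  sar <- render_sar(scn, d, noise = FALSE)
  sig_soil <- wcm_invert(db_to_linear(unclass(sar$sigma_can_db)),
                         unclass(sar$mveg_true), sar$theta_inc)
  sm <- apply_retrieval(retrieval_model(0.0133, 0.3815, "SM"),
                        linear_to_db(sig_soil))
  ids <- unclass(scn$field_map)
  truth <- wheatDA:::.truth_at(scn, d, "sm")
  for (f in c(2, 7, 11)) {
    px <- which(ids == f)[1]
    expect_equal(sm[px], truth[f], tolerance = 1e-6)
  }
  # wetter truth renders to stronger soil backscatter
  o <- order(truth)
  px <- vapply(o, function(f) which(ids == f)[1], integer(1))
  expect_true(all(diff(linear_to_db(sig_soil)[px]) > 0))
})

test_that("cloud-masked optical dates render fully nodata", {
  cfg <- scenario_config(seed = 6, n_fields = 12, frac_irrigated = 0.5,
                         grid_n = 24,
                         cloud_masked = as.Date("2019-04-01"))
  scn <- generate_truth(cfg)
  sc <- render_optical(scn, "2019-04-01")
  expect_true(all(is.na(sc$red)))
  expect_true(all(is.na(sc$nir)))
})

test_that("scene-level retrieval error sits near its configured target", {
  # replicated rendering: RMSE of retrieved vs truth within 30% of target
  lai_err <- sm_err <- numeric(6)
  for (i in seq_along(lai_err)) {
    scn <- generate_truth(scenario_config(seed = 20 + i, n_fields = 12,
                                          frac_irrigated = 0.5, grid_n = 24))
    d <- as.Date("2019-04-16")
    sc <- render_optical(scn, d)
    lai_g <- apply_retrieval(retrieval_model(8.8049, -0.9866, "LAI"),
                             ndvi(sc$red, sc$nir))
    ids <- unclass(scn$field_map)
    tl <- wheatDA:::.truth_grid(scn, wheatDA:::.truth_at(scn, d, "lai"), NA)
    lai_err[i] <- sqrt(mean((unclass(lai_g)[ids > 0] - tl[ids > 0])^2))
    sar <- render_sar(scn, "2019-04-19")
    opt0 <- render_optical(scn, "2019-04-19", noise = FALSE)
    mv <- mveg_from_ndwi(ndwi(opt0$nir, opt0$mir))
    ss <- wcm_invert(db_to_linear(unclass(sar$sigma_can_db)), unclass(mv),
                     sar$theta_inc)
    smr <- apply_retrieval(retrieval_model(0.0133, 0.3815, "SM"),
                           linear_to_db(pmax(1e-10, ss)))
    ts <- wheatDA:::.truth_grid(scn, wheatDA:::.truth_at(scn, "2019-04-19",
                                                         "sm"), NA)
    sm_err[i] <- sqrt(mean((smr[ids > 0] - ts[ids > 0])^2, na.rm = TRUE))
  }
  cfg <- scenario_config()
  expect_lt(abs(mean(lai_err) - cfg$target_lai_rmse) / cfg$target_lai_rmse,
            0.3)
  expect_lt(abs(mean(sm_err) - cfg$target_sm_rmse) / cfg$target_sm_rmse,
            0.3)
})

test_that("field campaign sampling matches the protocol", {
  scn <- generate_truth(scenario_config(seed = 13))
  sites <- sample_field_measurements(scn)
  expect_equal(nrow(sites), 45)
  expect_equal(sum(sites$regime == "irrigated"), 25)
  expect_equal(sum(sites$regime == "rain_fed"), 20)
  expect_equal(sum(sites$role == "cal" & sites$regime == "irrigated"), 10)
  expect_equal(sum(sites$role == "val" & sites$regime == "irrigated"), 15)
  expect_equal(sum(sites$role == "cal" & sites$regime == "rain_fed"), 10)
  expect_equal(sum(sites$role == "val" & sites$regime == "rain_fed"), 10)
  # roles reproducible under the seed
  sites2 <- sample_field_measurements(scn)
  expect_identical(sites$role, sites2$role)
})

test_that("noise-free field sampling returns the truth at the sampled dates", {
  cfg <- scenario_config(seed = 14, n_fields = 12, frac_irrigated = 0.5,
                         grid_n = 24, meas_lai_sd = 0, meas_sm_sd = 0,
                         meas_yield_sd = 0)
  scn <- generate_truth(cfg)
  sites <- sample_field_measurements(scn)
  jl <- wheatDA:::.truth_at(scn, cfg$meas_dates[["jointing"]], "lai")
  expect_equal(sites$lai_jointing, unname(jl[sites$field]), tolerance = 1e-9)
  expect_equal(sites$yield, scn$fields$yield[sites$field], tolerance = 1e-9)
})
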