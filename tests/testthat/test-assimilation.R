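test_that("ensemble perturbation has the configured relative spread", {
  soil <- soil_profile()
  cfg <- assim_config(n_ensemble = 500, seed = 9)
  state <- list(lai = 3, theta = rep(0.28, 7))
  ens <- perturb_ensemble(state, soil, cfg, seed = 9)
  expect_length(ens$lai, 500)
  rel_sd <- sd(ens$lai) / mean(ens$lai)
  # sampling tolerance: 3 * sd / sqrt(2 (n - 1))
  expect_lt(abs(rel_sd - cfg$sd_model_lai),
            3 * cfg$sd_model_lai / sqrt(2 * 499))
  rel_sd_sm <- sd(ens$theta[, 3]) / mean(ens$theta[, 3])
  expect_lt(abs(rel_sd_sm - cfg$sd_model_sm),
            3 * cfg$sd_model_sm / sqrt(2 * 499))
  # reproducible under the seed; degenerate n rejected
  ens2 <- perturb_ensemble(state, soil, cfg, seed = 9)
  expect_identical(ens, ens2)
  expect_error(perturb_ensemble(state, soil, cfg, n = 1), ">= 2")
})

test_that("near-zero perturbation leaves all members at the input state", {
  soil <- soil_profile()
  cfg <- assim_config(n_ensemble = 20, sd_model_lai = 1e-12,
                      sd_model_sm = 1e-12)
  ens <- perturb_ensemble(list(lai = 2, theta = rep(0.3, 7)), soil, cfg,
                          seed = 1)
  expect_equal(ens$lai, rep(2, 20), tolerance = 1e-9)
  expect_equal(unname(ens$theta[, 1]), rep(0.3, 20), tolerance = 1e-9)
})

test_that("deterministic update reproduces hand Kalman algebra", {
  # scalar state, members {1,2,3}: P = 1; obs 4 with sd 1 -> gain 0.5
  X <- matrix(c(1, 2, 3), ncol = 1)
  Xa <- enkf_update(X, 4, 1, matrix(1, 1, 1), perturb_obs = FALSE)
  expect_equal(mean(Xa), 3)
  # each member moves by gain x its own innovation
  expect_equal(as.numeric(Xa), c(2.5, 3, 3.5))
})

test_that("huge observation error gives the zero-gain limit", {
  set.seed(2)
  X <- matrix(rnorm(400, 5, 1), ncol = 2)
  Xa <- enkf_update(X, 10, 1e9, matrix(c(1, 0), 1, 2))
  expect_equal(colMeans(Xa), colMeans(X), tolerance = 1e-6)
})

test_that("tiny observation error pulls the observed component to the observation", {
  set.seed(3)
  X <- matrix(rnorm(1000, 5, 1), ncol = 1)
  Xa <- enkf_update(X, 7, 1e-6, matrix(1, 1, 1))
  expect_equal(mean(Xa), 7, tolerance = 1e-3)
})

test_that("analysis variance of the observed component shrinks", {
  set.seed(4)
  X <- matrix(rnorm(500, 5, 1), ncol = 1)
  Xa <- enkf_update(X, 5.5, 0.8, matrix(1, 1, 1))
  expect_lt(var(as.numeric(Xa)), var(as.numeric(X)))
})

test_that("stochastic EnKF converges to the exact Kalman filter", {
  # 1-D linear Gaussian system: prior N(2, 1.5), obs y = 3.2, R = 0.49
  set.seed(11)
  n <- 5000
  X <- matrix(rnorm(n, 2, sqrt(1.5)), ncol = 1)
  oracle <- kalman_oracle(mean(X), var(as.numeric(X)), 3.2, 0.49)
  Xa <- enkf_update(X, 3.2, 0.7, matrix(1, 1, 1))
  se_mean <- sqrt(oracle["var"] / n)
  expect_lt(abs(mean(Xa) - oracle["mean"]), 3 * se_mean)
  se_var <- oracle["var"] * sqrt(2 / (n - 1))
  expect_lt(abs(var(as.numeric(Xa)) - oracle["var"]), 3 * se_var)
})

test_that("multivariate update uses cross-covariances", {
  # two correlated components, only the first observed: the unobserved one
  # must move in proportion to the covariance
  set.seed(5)
  z <- rnorm(4000)
  X <- cbind(5 + z, 1 + 0.5 * z + rnorm(4000, 0, 0.1))
  Xa <- enkf_update(X, 8, 0.5, matrix(c(1, 0), 1, 2), perturb_obs = FALSE)
  shift1 <- mean(Xa[, 1]) - 5
  shift2 <- mean(Xa[, 2]) - 1
  expect_gt(shift1, 0)
  expect_equal(shift2 / shift1, 0.5, tolerance = 0.05)
})

test_that("an assimilation run without observations equals the open loop", {
  soil <- soil_profile()
  wx <- season_weather()
  mgmt <- management("2018-10-10")
  obs <- obs_table(as.Date(character()), character(), numeric())
  expect_warning(
    run <- assimilate(soil, wx, mgmt, crop_params(), obs,
                      assim_config(n_ensemble = 10, seed = 1)),
    "no observations")
  expect_equal(run$lai, run$lai_open, tolerance = 1e-12)
  expect_equal(run$sm, run$sm_open, tolerance = 1e-12)
  expect_equal(attr(run, "yield"), attr(run, "yield_open"),
               tolerance = 1e-12)
})

test_that("joint strategy with only LAI observations equals LAI_only", {
  soil <- soil_profile()
  wx <- season_weather()
  mgmt <- management("2018-10-10")
  obs <- obs_table(as.Date(c("2019-03-17", "2019-04-16")), c("LAI", "LAI"),
                   c(3, 6))
  r1 <- assimilate(soil, wx, mgmt, crop_params(), obs,
                   assim_config(n_ensemble = 30, seed = 3,
                                strategy = "joint"))
  r2 <- assimilate(soil, wx, mgmt, crop_params(), obs,
                   assim_config(n_ensemble = 30, seed = 3,
                                strategy = "LAI_only"))
  expect_equal(r1$lai, r2$lai, tolerance = 1e-12)
  expect_equal(attr(r1, "yield"), attr(r2, "yield"), tolerance = 1e-12)
})

test_that("assimilation runs are reproducible under (seed, config)", {
  soil <- soil_profile()
  wx <- season_weather()
  mgmt <- management("2018-10-10")
  obs <- obs_table(as.Date(c("2019-03-17", "2019-04-19")), c("LAI", "SM"),
                   c(3.5, 0.30))
  cfg <- assim_config(n_ensemble = 25, seed = 77)
  r1 <- assimilate(soil, wx, mgmt, crop_params(), obs, cfg)
  r2 <- assimilate(soil, wx, mgmt, crop_params(), obs, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # states stay physical and member count is conserved
  expect_false(any(is.na(r1$lai)))
  expect_true(all(r1$lai >= 0))
  expect_true(all(r1$sm >= 0 & r1$sm <= max(soil$theta_sat)))
  expect_length(attr(r1, "yield_members"), 25)
})

test_that("strategy filtering drops the other observation kind", {
  obs <- obs_table(as.Date(c("2019-03-01", "2019-03-13")), c("LAI", "SM"),
                   c(2, 0.3))
  expect_equal(wheatDA:::filter_obs_by_strategy(obs, "LAI_only")$kind, "LAI")
  expect_equal(wheatDA:::filter_obs_by_strategy(obs, "SM_only")$kind, "SM")
  expect_equal(nrow(wheatDA:::filter_obs_by_strategy(obs, "joint")), 2)
})

test_that("observation operator maps LAI and 0-20 cm moisture components", {
  soil <- soil_profile()
  H <- wheatDA:::obs_operator(c("LAI", "SM"), soil)
  expect_equal(dim(H), c(2, 8))
  expect_equal(H[1, ], c(1, rep(0, 7)))
  expect_equal(H[2, ], c(0, 0.5, 0.5, rep(0, 5)))
})
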