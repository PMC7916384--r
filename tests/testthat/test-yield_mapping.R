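test_that("printed stage-weight sets are valid and sum to one", {
  w_lai <- stage_weights("LAI")
  w_sm <- stage_weights("SM")
  expect_equal(sum(w_lai), 1, tolerance = 1e-6)
  expect_equal(sum(w_sm), 1, tolerance = 1e-6)
  expect_equal(unname(w_lai[["heading_filling"]]), 0.5660)
  expect_equal(unname(w_sm[["jointing"]]), 0.5655)
  expect_error(stage_weights("LAI", c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(stage_weights("LAI", c(-0.1, 0.4, 0.4, 0.3)), "non-negative")
})

test_that("stage composite is the weighted dot product and is linear", {
  w <- stage_weights("LAI")
  expect_equal(stage_composite(c(green_up = 2, jointing = 2,
                                 heading_filling = 2, milking = 2), w), 2)
  expect_equal(stage_composite(c(green_up = 0, jointing = 0,
                                 heading_filling = 1, milking = 0), w),
               0.5660)
  v <- c(green_up = 1, jointing = 2, heading_filling = 4, milking = 3)
  expect_equal(stage_composite(v, w), 3.191, tolerance = 1e-9)
  expect_equal(stage_composite(3 * v, w), 3 * stage_composite(v, w))
  expect_error(stage_composite(v[-2], w), "jointing")
  # matrix form, one row per site
  m <- rbind(v, 2 * v)
  expect_equal(stage_composite(m, w), c(3.191, 6.382), tolerance = 1e-9)
})

test_that("yield regression recovers generating coefficients exactly", {
  set.seed(8)
  lai <- runif(12, 2, 6)
  y <- 1041.9 * lai + 1031.4
  m <- suppressWarnings(
    fit_yield_model(data.frame(lai = lai), y, "irrigated", "LAI_only"))
  expect_equal(unname(coef(m)), c(1031.4, 1041.9), tolerance = 1e-6)
  expect_equal(m$r2, 1)
  # two-predictor model, matches the normal-equations oracle
  sm <- runif(12, 0.2, 0.35)
  y2 <- 967.2 * lai + 4922.6 * sm + 688.6 + rnorm(12, 0, 50)
  m2 <- fit_yield_model(data.frame(lai = lai, sm = sm), y2, "rain_fed",
                        "joint")
  o <- ols_oracle(cbind(lai, sm), y2)
  expect_equal(unname(coef(m2)), unname(o), tolerance = 1e-9)
  # fitted values on the training sites reproduce OLS predictions
  expect_equal(predict(m2, data.frame(lai = lai, sm = sm)),
               unname(fitted(m2$fit)), tolerance = 1e-9)
})

test_that("degenerate yield fits are rejected", {
  lai <- c(1, 2, 3, 4, 5)
  expect_error(fit_yield_model(data.frame(lai = lai, sm = lai),
                               1000 * lai, "rain_fed", "joint"),
               "collinear")
  expect_error(fit_yield_model(data.frame(lai = rep(2, 5)), 1:5 * 1000,
                               "irrigated", "LAI_only"), "constant")
  expect_error(fit_yield_model(data.frame(lai = 1:3), c(1, 2, 3) * 1000,
                               "irrigated", "joint"), "lack")
})

test_that("raster yield prediction respects regime masks and clamps", {
  m <- suppressWarnings(
    fit_yield_model(data.frame(lai = c(1, 2, 3, 4, 6)),
                    1041.9 * c(1, 2, 3, 4, 6) + 1031.4,
                    "irrigated", "LAI_only"))
  expect_equal(predict(m, list(lai = 3)), 4157.1, tolerance = 1e-6)
  comp <- grid_raster(matrix(0, 2, 2))
  expect_equal(unclass(predict(m, list(lai = comp)))[1, 1], 1031.4,
               tolerance = 1e-6)
  # regime masking: pixels outside the model's regime become nodata
  rm <- grid_raster(matrix(c(1, 2, 0, NA), 2, 2))
  class(rm) <- c("regime_mask", class(rm))
  out <- predict(m, list(lai = grid_raster(matrix(3, 2, 2))),
                 regime_mask = rm)
  expect_equal(out[1, 1], 4157.1, tolerance = 1e-6)
  expect_true(is.na(out[2, 1]))  # rain-fed pixel
  expect_true(is.na(out[1, 2]))  # non-wheat pixel
  expect_true(is.na(out[2, 2]))  # nodata pixel
})

test_that("validation metrics match hand arithmetic and reject bad input", {
  v <- validate_yield(c(1100, 900), c(1000, 1000))
  expect_equal(v$rmse, 100)
  expect_equal(v$are, 10)
  v0 <- validate_yield(c(500, 800, 900), c(500, 800, 900))
  expect_equal(v0$rmse, 0)
  expect_equal(v0$are, 0)
  expect_error(validate_yield(1000, 900), "2")
  expect_error(validate_yield(c(1, 2), c(0, 2)), "positive")
  expect_error(validate_yield(c(1, 2, 3), c(1, 2)), "unpaired")
})

test_that("strategy ranking reproduces the published ordering from its table", {
  reports <- data.frame(
    regime = rep(c("irrigated", "rain_fed"), each = 3),
    strategy = rep(c("LAI_only", "SM_only", "joint"), 2),
    rmse = c(427.57, 533.64, 436.71, 612.93, 467.37, 424.75),
    are = c(6.07, 8.49, 6.16, 12.47, 11.44, 9.55))
  cmp <- compare_strategies(reports)
  w <- attr(cmp, "winners")
  expect_equal(unname(w[["irrigated"]]), "LAI_only")
  expect_equal(unname(w[["rain_fed"]]), "joint")
})

test_that("ties break deterministically and are flagged", {
  reports <- data.frame(regime = "irrigated",
                        strategy = c("joint", "LAI_only"),
                        rmse = c(500, 500), are = c(5, 5))
  cmp <- compare_strategies(reports)
  expect_equal(attr(cmp, "winners")[["irrigated"]], "LAI_only")
  expect_true(all(cmp$tie))
  expect_warning(compare_strategies(
    data.frame(regime = "rain_fed", strategy = "joint", rmse = 1, are = 1)),
    "single strategy")
})
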