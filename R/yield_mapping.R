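#' Phenological stage weights
#'
#' Relative contribution of the four main growth stages (green-up, jointing,
#' heading-filling, milking) to final yield, used to collapse a seasonal
#' LAI or soil-moisture profile into a single stage-weighted composite.
#' Defaults are the analytic-hierarchy weights for winter wheat: LAI
#' 0.0550/0.2650/0.5660/0.1140 and soil moisture 0.0555/0.5655/0.2605/0.1185.
#' Weights must be non-negative and sum to 1 (checked to 1e-6).
#'
#' @param kind `"LAI"` or `"SM"`.
#' @param weights optional numeric(4), ordered green-up, jointing,
#'   heading-filling, milking.
#' @return an object of class `stage_weights`.
#' @export
stage_weights <- function(kind = c("LAI", "SM"), weights = NULL) {
  kind <- match.arg(kind)
  if (is.null(weights))
    weights <- if (kind == "LAI") c(0.0550, 0.2650, 0.5660, 0.1140)
               else c(0.0555, 0.5655, 0.2605, 0.1185)
  if (length(weights) != 4 || any(weights < 0))
    stop("need 4 non-negative stage weights")
  if (abs(sum(weights) - 1) > 1e-6)
    stop("stage weights must sum to 1 (got ", sum(weights), ")")
  structure(stats::setNames(weights, COMPOSITE_STAGES), kind = kind,
            class = "stage_weights")
}

#' Stage-weighted composite
#'
#' Dot product of per-stage values with the stage weights; since weights sum
#' to one the composite has the units of the input variable.
#'
#' @param values named numeric(4) (names `green_up`, `jointing`,
#'   `heading_filling`, `milking`) or a 4-column matrix / data.frame with one
#'   row per site.
#' @param w a [stage_weights()].
#' @return composite value(s), same units as `values`.
#' @export
stage_composite <- function(values, w) {
  stopifnot(inherits(w, "stage_weights"))
  if (is.data.frame(values)) values <- as.matrix(values)
  if (is.matrix(values)) {
    miss <- setdiff(COMPOSITE_STAGES, colnames(values))
    if (length(miss)) stop("missing stage: ", paste(miss, collapse = ", "))
    return(as.numeric(values[, COMPOSITE_STAGES, drop = FALSE] %*%
                        as.numeric(w)))
  }
  if (!is.null(names(values))) {
    miss <- setdiff(COMPOSITE_STAGES, names(values))
    if (length(miss)) stop("missing stage: ", paste(miss, collapse = ", "))
    values <- values[COMPOSITE_STAGES]
  } else if (length(values) != 4) {
    stop("missing stage: need all four stage values")
  }
  sum(as.numeric(values) * as.numeric(w))
}

#' Fit a stage-composite yield regression
#'
#' Ordinary least squares of measured site yield on the stage-weighted
#' composite predictors: the LAI composite (`LAI_only`), the soil-moisture
#' composite (`SM_only`), or both (`joint`). Significance of the model is
#' classed `*` / `**` / `***` at p < 0.05 / 0.01 / 0.001.
#'
#' @param composites data.frame with columns `lai` and/or `sm` (one row per
#'   calibration site).
#' @param yields measured yields, kg ha-1.
#' @param regime `"irrigated"` or `"rain_fed"`.
#' @param strategy `"LAI_only"`, `"SM_only"` or `"joint"`.
#' @return an object of class `yield_model` with `coefficients`, `r2`,
#'   `p_value`, `p_class`, `n`.
#' @export
fit_yield_model <- function(composites, yields,
                            regime = c("irrigated", "rain_fed"),
                            strategy = c("LAI_only", "SM_only", "joint")) {
  regime <- match.arg(regime)
  strategy <- match.arg(strategy)
  vars <- switch(strategy, LAI_only = "lai", SM_only = "sm",
                 joint = c("lai", "sm"))
  miss <- setdiff(vars, names(composites))
  if (length(miss)) stop("composites lack column(s): ",
                         paste(miss, collapse = ", "))
  df <- data.frame(y = yields, composites[vars])
  if (nrow(df) < length(vars) + 2)
    stop("need at least ", length(vars) + 2, " sites")
  X <- as.matrix(df[vars])
  if (length(vars) == 2 && abs(stats::cor(X[, 1], X[, 2])) > 1 - 1e-10)
    stop("collinear predictors")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant predictor")
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  p_class <- if (p < 0.001) "***" else if (p < 0.01) "**"
             else if (p < 0.05) "*" else "ns"
  structure(list(coefficients = stats::coef(fit), r2 = sm$r.squared,
                 p_value = p, p_class = p_class, n = nrow(df),
                 regime = regime, strategy = strategy, fit = fit),
            class = "yield_model")
}

#' @export
print.yield_model <- function(x, ...) {
  cf <- x$coefficients
  terms <- paste(sprintf("%.1f x %s", cf[-1], names(cf)[-1]),
                 collapse = " + ")
  cat(sprintf("yield_model [%s, %s]: Y = %s + %.1f\n", x$regime, x$strategy,
              terms, cf[1]))
  cat(sprintf("  n = %d, R2 = %.2f, p %s\n", x$n, x$r2, x$p_class))
  invisible(x)
}

#' @export
coef.yield_model <- function(object, ...) object$coefficients

#' Predict yield from composite rasters or site composites
#'
#' Applies a fitted [fit_yield_model()] per pixel (or per site row), clamped
#' at zero. With rasters, nodata pixels propagate; pixels outside the model's
#' regime (per `regime_mask`) come back as nodata.
#'
#' @param object a `yield_model`.
#' @param newdata named list or data.frame with elements `lai` and/or `sm`
#'   ([grid_raster()]s or vectors).
#' @param regime_mask optional [grid_raster()] of regime codes (see
#'   [regime_split()]); pixels whose code does not match the model's regime
#'   are masked.
#' @param ... unused.
#' @return predicted yield, kg ha-1, same shape as the inputs.
#' @export
predict.yield_model <- function(object, newdata, regime_mask = NULL, ...) {
  vars <- names(object$coefficients)[-1]
  miss <- setdiff(vars, names(newdata))
  if (length(miss)) stop("newdata lacks: ", paste(miss, collapse = ", "))
  first <- newdata[[vars[1]]]
  is_grid <- inherits(first, "grid_raster")
  acc <- object$coefficients[1]
  for (v in vars) {
    xv <- newdata[[v]]
    if (is_grid) check_aligned(first, xv)
    acc <- acc + object$coefficients[[v]] *
      (if (inherits(xv, "grid_raster")) unclass(xv) else xv)
  }
  out <- pmax(0, acc)
  if (!is.null(regime_mask)) {
    if (!is_grid) stop("regime_mask applies to raster prediction only")
    check_aligned(first, regime_mask)
    code <- REGIME_CODES[[object$regime]]
    out[is.na(regime_mask) | unclass(regime_mask) != code] <- NA_real_
  }
  if (is_grid) same_grid(first, out) else as.numeric(out)
}

#' Compose a regional yield map from per-regime models
#'
#' Applies the irrigated model over irrigated pixels and the rain-fed model
#' over rain-fed pixels of one regime mask; non-wheat pixels stay nodata.
#'
#' @param models named list with elements `irrigated` and `rain_fed`, each a
#'   `yield_model`.
#' @param composites list with `lai` and/or `sm` composite rasters.
#' @param regime_mask [grid_raster()] of regime codes.
#' @return yield raster, kg ha-1.
#' @export
predict_yield_map <- function(models, composites, regime_mask) {
  irr <- predict(models$irrigated, composites, regime_mask)
  rf <- predict(models$rain_fed, composites, regime_mask)
  out <- unclass(irr)
  take <- is.na(out) & !is.na(unclass(rf))
  out[take] <- unclass(rf)[take]
  same_grid(regime_mask, out)
}

#' Yield validation metrics
#'
#' Root mean square error and mean absolute relative error between predicted
#' and measured site yields: `RMSE = sqrt(mean((p - m)^2))`,
#' `ARE = 100 * mean(|p - m| / m)` (per-site relative errors averaged, in
#' percent).
#'
#' @param predicted,measured paired site yields, kg ha-1 (`n >= 2`; measured
#'   values must be positive).
#' @return an object of class `yield_validation` with `rmse`, `are`,
#'   `n_sites`, `residuals`.
#' @export
validate_yield <- function(predicted, measured) {
  if (length(predicted) != length(measured)) stop("unpaired site vectors")
  if (length(predicted) < 2) stop("need at least 2 validation sites")
  if (any(measured <= 0)) stop("measured yields must be positive")
  r <- predicted - measured
  structure(list(rmse = sqrt(mean(r^2)),
                 are = 100 * mean(abs(r) / measured),
                 n_sites = length(r), residuals = r),
            class = "yield_validation")
}

#' @export
print.yield_validation <- function(x, ...) {
  cat(sprintf("yield validation over %d sites: RMSE %.2f kg/ha, ARE %.2f%%\n",
              x$n_sites, x$rmse, x$are))
  invisible(x)
}

#' Rank assimilation strategies per water regime
#'
#' Orders strategies by validation RMSE (ties broken by ARE, then by the
#' strategy factor order, flagged) and names the recommended strategy for
#' each regime.
#'
#' @param reports data.frame with columns `regime`, `strategy`, `rmse`,
#'   `are`.
#' @return an object of class `strategy_comparison`: the ranked table with
#'   attribute `winners` (named character vector, one strategy per regime).
#' @export
compare_strategies <- function(reports) {
  need <- c("regime", "strategy", "rmse", "are")
  if (!all(need %in% names(reports)))
    stop("reports need columns ", paste(need, collapse = ", "))
  strat_order <- c("LAI_only", "SM_only", "joint")
  reports$strategy <- as.character(reports$strategy)
  out <- do.call(rbind, lapply(split(reports, reports$regime), function(d) {
    if (nrow(d) < 2)
      warning("single strategy for regime ", d$regime[1],
              "; returned as winner")
    o <- order(d$rmse, d$are, match(d$strategy, strat_order))
    d <- d[o, , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d$tie <- duplicated(d[c("rmse", "are")]) |
      duplicated(d[c("rmse", "are")], fromLast = TRUE)
    d
  }))
  rownames(out) <- NULL
  winners <- vapply(split(out, out$regime),
                    function(d) d$strategy[d$rank == 1], character(1))
  structure(out, winners = winners,
            class = c("strategy_comparison", "data.frame"))
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("strategy comparison (rank 1 = recommended):\n")
  print.data.frame(x)
  w <- attr(x, "winners")
  for (r in names(w)) cat(sprintf("  %s: use %s\n", r, w[[r]]))
  invisible(x)
}
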