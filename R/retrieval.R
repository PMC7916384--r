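# Division guarded against near-zero denominators: masked, not extrapolated.
.safe_ratio <- function(num, den, eps = 1e-12) {
  out <- ifelse(is.na(num) | is.na(den) | abs(den) <= eps, NA_real_,
                num / den)
  out
}

#' Normalized difference vegetation index
#'
#' `(nir - red) / (nir + red)`. Pixels where the denominator is ~0 or either
#' band is nodata come back as nodata.
#'
#' @param red,nir surface reflectance in `[0, 1]`; scalars, vectors or
#'   [grid_raster()]s on one grid.
#' @return NDVI in `[-1, 1]`, same shape as the inputs.
#' @export
ndvi <- function(red, nir) {
  if (inherits(red, "grid_raster")) check_aligned(red, nir)
  out <- .safe_ratio(nir - red, nir + red)
  if (all(is.na(out))) stop("NDVI: all pixels are nodata")
  if (inherits(red, "grid_raster")) same_grid(red, out) else out
}

#' Normalized difference water index
#'
#' `(nir - mir) / (nir + mir)`, sensitive to canopy water content.
#'
#' @param nir,mir near- and mid-infrared surface reflectance in `[0, 1]`.
#' @return NDWI in `[-1, 1]`, same shape as the inputs.
#' @export
ndwi <- function(nir, mir) {
  if (inherits(nir, "grid_raster")) check_aligned(nir, mir)
  out <- .safe_ratio(nir - mir, nir + mir)
  if (all(is.na(out))) stop("NDWI: all pixels are nodata")
  if (inherits(nir, "grid_raster")) same_grid(nir, out) else out
}

#' Vegetation water content from NDWI
#'
#' Empirical quadratic relating canopy water content to NDWI:
#' `m_veg = 1.44 NDWI^2 + 1.36 NDWI + 0.34`, clamped at zero.
#'
#' @param x NDWI in `[-1, 1]` (vector or [grid_raster()]).
#' @return vegetation water content, kg m-2.
#' @export
mveg_from_ndwi <- function(x) {
  v <- if (inherits(x, "grid_raster")) unclass(x) else x
  if (any(abs(v) > 1 + 1e-9, na.rm = TRUE))
    stop("NDWI outside [-1, 1]")
  out <- pmax(0, 1.44 * v^2 + 1.36 * v + 0.34)
  if (inherits(x, "grid_raster")) same_grid(x, out) else out
}

# Inverse of mveg_from_ndwi on its increasing branch (NDWI >= -1.36/2.88);
# used only by the scene renderer, which stays on that branch.
ndwi_from_mveg <- function(m) {
  disc <- 1.36^2 - 4 * 1.44 * (0.34 - m)
  if (any(disc < 0, na.rm = TRUE)) stop("m_veg below the polynomial minimum")
  (-1.36 + sqrt(disc)) / (2 * 1.44)
}

#' Two-way canopy attenuation of the water cloud model
#' @param m_veg vegetation water content, kg m-2.
#' @param theta_inc microwave incidence angle, degrees in `[0, 90)`.
#' @param B canopy attenuation parameter.
#' @return gamma-squared in `(0, 1]`.
#' @export
wcm_gamma2 <- function(m_veg, theta_inc, B) {
  if (any(theta_inc < 0 | theta_inc >= 90, na.rm = TRUE))
    stop("incidence angle must be in [0, 90) degrees")
  exp(-2 * B * m_veg / cos(theta_inc * pi / 180))
}

#' Water cloud model parameters
#' @param A vegetation scattering coefficient (winter wheat 0.0018).
#' @param B canopy attenuation coefficient (winter wheat 0.138).
#' @return an object of class `wcm_params`.
#' @export
wcm_params <- function(A = 0.0018, B = 0.138) {
  stopifnot(A >= 0, B > 0)
  structure(list(A = A, B = B), class = "wcm_params")
}

#' Water cloud model, forward direction
#'
#' Total canopy backscatter as direct vegetation scattering plus soil
#' backscatter attenuated twice by the canopy:
#' `sigma_can = A m_veg cos(theta) (1 - gamma2) + gamma2 sigma_soil`,
#' `gamma2 = exp(-2 B m_veg sec(theta))`. All backscatter in linear power.
#'
#' @param sigma_soil soil backscattering coefficient, linear power.
#' @param m_veg vegetation water content, kg m-2 (`>= 0`).
#' @param theta_inc incidence angle, degrees.
#' @param params a [wcm_params()].
#' @return canopy backscatter, linear power.
#' @export
wcm_forward <- function(sigma_soil, m_veg, theta_inc, params = wcm_params()) {
  if (any(m_veg < 0, na.rm = TRUE)) stop("m_veg must be >= 0")
  g2 <- wcm_gamma2(m_veg, theta_inc, params$B)
  params$A * m_veg * cos(theta_inc * pi / 180) * (1 - g2) + g2 * sigma_soil
}

#' Water cloud model, inverse direction
#'
#' Removes the vegetation contribution from total backscatter to recover the
#' direct soil backscatter: `(sigma_can - sigma_veg) / gamma2`. The exact
#' algebraic inverse of [wcm_forward()]. Pixels whose canopy attenuates below
#' `eps` (dense canopy, no soil signal) are masked rather than extrapolated.
#'
#' @param sigma_can total canopy backscatter, linear power.
#' @param m_veg vegetation water content, kg m-2.
#' @param theta_inc incidence angle, degrees.
#' @param params a [wcm_params()].
#' @param eps smallest invertible attenuation.
#' @return soil backscatter, linear power (NA where masked).
#' @export
wcm_invert <- function(sigma_can, m_veg, theta_inc, params = wcm_params(),
                       eps = 1e-6) {
  if (any(m_veg < 0, na.rm = TRUE)) stop("m_veg must be >= 0")
  ct <- cos(theta_inc * pi / 180)
  g2 <- wcm_gamma2(m_veg, theta_inc, params$B)
  out <- (sigma_can - params$A * m_veg * ct * (1 - g2)) / g2
  out[!is.na(g2) & g2 <= eps] <- NA_real_
  out
}

#' dB / linear power conversions
#'
#' `db_to_linear(x) = 10^(x/10)`; `linear_to_db(x) = 10 log10(x)`. SAR scene
#' files carry dB (the Sentinel-1 convention); the water cloud model operates
#' in linear power.
#'
#' @param x backscatter in dB (resp. linear power `> 0`).
#' @return linear power (resp. dB).
#' @export
db_to_linear <- function(x) 10^(x / 10)

#' @rdname db_to_linear
#' @export
linear_to_db <- function(x) {
  if (any(x <= 0, na.rm = TRUE))
    stop("linear power must be positive for dB conversion")
  10 * log10(x)
}

#' Fit an empirical linear retrieval model
#'
#' Ordinary least squares of a field-measured target (LAI or soil moisture)
#' on a remote-sensing predictor (NDVI or soil backscatter), as used to
#' calibrate scene-to-variable retrievals on a single overpass date.
#'
#' @param x predictor samples at the field sites.
#' @param y target samples (LAI, m2 m-2, or soil moisture, cm3 cm-3).
#' @param target `"LAI"` or `"SM"`; sets the physical clamp used on
#'   prediction.
#' @param date optional calibration date, carried as provenance.
#' @return an object of class `retrieval_model` with `slope`, `intercept`,
#'   `r2`, `rmse`, `p_value`, `n`.
#' @export
fit_retrieval <- function(x, y, target = c("LAI", "SM"), date = NULL) {
  target <- match.arg(target)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite samples")
  if (stats::sd(x) == 0) stop("zero predictor variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared,
                 rmse = sqrt(mean(stats::residuals(fit)^2)),
                 p_value = unname(sm$coefficients[2, 4]),
                 n = length(x), target = target, date = date),
            class = "retrieval_model")
}

#' Construct a retrieval model from known coefficients
#'
#' For applying published slope/intercept pairs (e.g. an NDVI-LAI or
#' backscatter-moisture regression calibrated elsewhere) without refitting.
#'
#' @param slope,intercept linear coefficients.
#' @inheritParams fit_retrieval
#' @return a `retrieval_model`.
#' @export
retrieval_model <- function(slope, intercept, target = c("LAI", "SM")) {
  target <- match.arg(target)
  structure(list(slope = slope, intercept = intercept, r2 = NA_real_,
                 rmse = NA_real_, p_value = NA_real_, n = NA_integer_,
                 target = target, date = NULL),
            class = "retrieval_model")
}

#' @export
print.retrieval_model <- function(x, ...) {
  cat(sprintf("retrieval_model (%s): y = %.4f x + %.4f\n", x$target,
              x$slope, x$intercept))
  if (is.finite(x$r2))
    cat(sprintf("  n = %d, R2 = %.3f, RMSE = %.4f, p = %.3g\n",
                x$n, x$r2, x$rmse, x$p_value))
  invisible(x)
}

#' @export
coef.retrieval_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Apply a linear retrieval to a predictor field
#'
#' `slope * x + intercept`, clamped to the target's physical range (LAI
#' `>= 0`; soil moisture in `[0, 0.6]` cm3 cm-3). Nodata propagates.
#'
#' @param model a `retrieval_model`.
#' @param x predictor values (vector or [grid_raster()]).
#' @return retrieved target, same shape as `x`.
#' @export
apply_retrieval <- function(model, x) {
  v <- if (inherits(x, "grid_raster")) unclass(x) else x
  out <- model$slope * v + model$intercept
  out <- if (model$target == "LAI") pmax(0, out) else pmin(0.6, pmax(0, out))
  if (inherits(x, "grid_raster")) same_grid(x, out) else out
}

#' @export
predict.retrieval_model <- function(object, newdata, ...) {
  apply_retrieval(object, newdata)
}

#' Serialize / restore a retrieval model as YAML
#' @param model a `retrieval_model`.
#' @param path file path.
#' @return `path` (write) or a `retrieval_model` (read).
#' @export
write_retrieval_yaml <- function(model, path) {
  yaml::write_yaml(unclass(model), path, precision = 12)
  invisible(path)
}

#' @rdname write_retrieval_yaml
#' @export
read_retrieval_yaml <- function(path) {
  structure(yaml::read_yaml(path), class = "retrieval_model")
}
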