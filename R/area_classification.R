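# Integer codes written into regime-mask rasters.
REGIME_CODES <- c(non_wheat = 0L, irrigated = 1L, rain_fed = 2L)

#' Decision-tree winter wheat mask from multi-temporal NDVI
#'
#' A pixel is winter wheat when it is green in mid-March and mid-April
#' (NDVI above the threshold on both dates), harvested by June (NDVI below
#' the threshold), and declining from April to June. Summer crops fail the
#' June test; bare ground fails the spring tests.
#'
#' @param ndvi_t1 NDVI raster, mid-March.
#' @param ndvi_t2 NDVI raster, mid-April.
#' @param ndvi_t3 NDVI raster, June (post-harvest).
#' @param threshold NDVI decision threshold (default 0.25).
#' @return logical [grid_raster()] (`NA` where any input is nodata).
#' @export
wheat_mask <- function(ndvi_t1, ndvi_t2, ndvi_t3, threshold = 0.25) {
  check_aligned(ndvi_t1, ndvi_t2)
  check_aligned(ndvi_t1, ndvi_t3)
  out <- (unclass(ndvi_t1) > threshold) & (unclass(ndvi_t2) > threshold) &
    (unclass(ndvi_t3) < threshold) & (unclass(ndvi_t2) > unclass(ndvi_t3))
  same_grid(ndvi_t1, as.numeric(out))
}

#' Terrain grid
#' @param elevation elevation raster, m.
#' @param slope slope raster, degrees in `[0, 90]`; derived from the
#'   elevation raster by central finite differences when omitted.
#' @return an object of class `terrain_grid` (list of two aligned rasters).
#' @export
terrain_grid <- function(elevation, slope = NULL) {
  if (is.null(slope)) slope <- slope_from_dem(elevation)
  check_aligned(elevation, slope)
  if (any(unclass(slope) < 0 | unclass(slope) > 90, na.rm = TRUE))
    stop("slope must be within [0, 90] degrees")
  structure(list(elevation = elevation, slope = slope),
            class = "terrain_grid")
}

#' Slope from a DEM by central finite differences
#' @param dem elevation [grid_raster()], m.
#' @return slope raster, degrees.
#' @export
slope_from_dem <- function(dem) {
  z <- unclass(dem)
  cs <- attr(dem, "cellsize")
  pad <- function(m, dr, dc) {
    r <- pmin(pmax(seq_len(nrow(m)) + dr, 1), nrow(m))
    c <- pmin(pmax(seq_len(ncol(m)) + dc, 1), ncol(m))
    m[r, c, drop = FALSE]
  }
  dzdx <- (pad(z, 0, 1) - pad(z, 0, -1)) / (2 * cs)
  dzdy <- (pad(z, 1, 0) - pad(z, -1, 0)) / (2 * cs)
  same_grid(dem, atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi)
}

#' Split the wheat mask into irrigated and rain-fed regimes
#'
#' Wheat pixels on low, flat terrain (elevation below `elev_thresh` and slope
#' below `slope_thresh`) are classed irrigated; every other wheat pixel is
#' rain-fed, so the two regimes partition the wheat area. Non-wheat pixels
#' keep code 0.
#'
#' @param wheat logical wheat raster from [wheat_mask()].
#' @param terrain a [terrain_grid()].
#' @param elev_thresh elevation threshold, m (default 600).
#' @param slope_thresh slope threshold, degrees (default 15).
#' @return [grid_raster()] of regime codes (0 non-wheat, 1 irrigated,
#'   2 rain-fed), class `regime_mask`.
#' @export
regime_split <- function(wheat, terrain, elev_thresh = 600,
                         slope_thresh = 15) {
  check_aligned(wheat, terrain$elevation)
  w <- unclass(wheat) > 0
  irr <- w & (unclass(terrain$elevation) < elev_thresh) &
    (unclass(terrain$slope) < slope_thresh)
  code <- matrix(REGIME_CODES[["non_wheat"]], nrow(w), ncol(w))
  code[w] <- REGIME_CODES[["rain_fed"]]
  code[irr] <- REGIME_CODES[["irrigated"]]
  code[is.na(w)] <- NA_real_
  out <- same_grid(wheat, code)
  class(out) <- c("regime_mask", class(out))
  out
}

#' Per-class areas and wheat-area shares
#'
#' Pixel counts times pixel area per regime class, and each regime's share of
#' the total wheat area in percent (reported to one decimal).
#'
#' @param mask a regime mask from [regime_split()] (or a data.frame with
#'   columns `class`, `area_ha` of pre-computed areas).
#' @param pixel_area_ha override for the per-pixel area, ha.
#' @return data.frame with columns `class`, `n_pixels`, `area_ha`,
#'   `share_pct` (share of wheat area; `NA` for non-wheat). A mask with no
#'   wheat pixels yields `NA` shares with a warning.
#' @export
class_areas <- function(mask, pixel_area_ha = NULL) {
  if (is.data.frame(mask)) {
    out <- mask[c("class", "area_ha")]
    out$n_pixels <- NA_integer_
  } else {
    if (is.null(pixel_area_ha)) pixel_area_ha <- pixel_area_ha(mask)
    cnt <- vapply(REGIME_CODES, function(cd)
      sum(unclass(mask) == cd, na.rm = TRUE), numeric(1))
    out <- data.frame(class = names(REGIME_CODES), n_pixels = cnt,
                      area_ha = cnt * pixel_area_ha)
  }
  wheat_rows <- out$class %in% c("irrigated", "rain_fed")
  total <- sum(out$area_ha[wheat_rows])
  if (total == 0) {
    warning("empty wheat mask: shares undefined")
    out$share_pct <- NA_real_
  } else {
    out$share_pct <- ifelse(wheat_rows,
                            round(100 * out$area_ha / total, 1), NA_real_)
  }
  rownames(out) <- NULL
  out
}
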