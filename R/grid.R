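#' Matrix-backed raster grid
#'
#' A minimal single-band raster: a numeric matrix (rows = northing, top row =
#' northern edge; columns = easting) carrying grid geometry as attributes.
#' `NA` cells are nodata and propagate through every raster operation in the
#' package. Values are stored row-major as R matrices; geometry follows the
#' ESRI ASCII grid convention (lower-left corner origin, square cells).
#'
#' @param values numeric matrix (or vector with `nrow`/`ncol`).
#' @param xll,yll coordinates of the lower-left corner (m).
#' @param cellsize square pixel edge length (m).
#' @param crs free-text coordinate reference tag carried along, never
#'   interpreted.
#' @param nrow,ncol grid dimensions when `values` is not already a matrix.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, xll = 0, yll = 0, cellsize = 100,
                        crs = "local", nrow = NULL, ncol = NULL) {
  if (!is.matrix(values)) {
    if (is.null(nrow) || is.null(ncol))
      stop("values must be a matrix, or nrow/ncol must be given")
    values <- matrix(as.numeric(values), nrow = nrow, ncol = ncol)
  }
  storage.mode(values) <- "double"
  stopifnot(is.finite(cellsize), cellsize > 0)
  structure(values,
            xll = xll, yll = yll, cellsize = cellsize, crs = crs,
            class = c("grid_raster", "matrix", "array"))
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster: %d x %d cells, cellsize %g m, origin (%g, %g)\n",
              nrow(x), ncol(x), attr(x, "cellsize"),
              attr(x, "xll"), attr(x, "yll")))
  v <- x[!is.na(x)]
  if (length(v))
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g; %d nodata cells\n",
                min(v), mean(v), max(v), sum(is.na(x))))
  else cat("  all cells nodata\n")
  invisible(x)
}

#' Pixel area in hectares
#' @param x a `grid_raster`.
#' @return scalar area of one pixel, ha.
#' @export
pixel_area_ha <- function(x) attr(x, "cellsize")^2 / 1e4

#' Check that two grids share dimensions and geometry
#' @param a,b `grid_raster` objects.
#' @param tol geometry tolerance in metres.
#' @return `TRUE` invisibly; errors if misaligned.
#' @export
check_aligned <- function(a, b, tol = 1e-6) {
  if (!identical(dim(a), dim(b)))
    stop("grids are misaligned: dimensions differ")
  geo <- function(g) c(attr(g, "xll"), attr(g, "yll"), attr(g, "cellsize"))
  if (any(abs(geo(a) - geo(b)) > tol))
    stop("grids are misaligned: geometry differs")
  invisible(TRUE)
}

# Rebuild a grid_raster with the same geometry but new cell values.
same_grid <- function(template, values) {
  grid_raster(matrix(values, nrow = nrow(template), ncol = ncol(template)),
              xll = attr(template, "xll"), yll = attr(template, "yll"),
              cellsize = attr(template, "cellsize"), crs = attr(template, "crs"))
}

#' Write a grid to an ESRI ASCII grid (.asc) file
#'
#' Plain-text raster interchange: a six-line header followed by rows of cell
#' values from the northern edge down, nodata written as -9999.
#'
#' @param x a `grid_raster`.
#' @param path output file path.
#' @param digits significant digits written.
#' @return `path` invisibly.
#' @export
write_asc <- function(x, path, digits = 10) {
  stopifnot(inherits(x, "grid_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(x)),
    sprintf("nrows %d", nrow(x)),
    sprintf("xllcorner %.10g", attr(x, "xll")),
    sprintf("yllcorner %.10g", attr(x, "yll")),
    sprintf("cellsize %.10g", attr(x, "cellsize")),
    "NODATA_value -9999"), con)
  m <- unclass(x)
  m[is.na(m)] <- -9999
  for (i in seq_len(nrow(m)))
    writeLines(paste(signif(m[i, ], digits), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid (.asc) file
#' @param path file path.
#' @param crs coordinate reference tag to attach.
#' @return a `grid_raster`.
#' @export
read_asc <- function(path, crs = "local") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed .asc header in ", path)
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(body, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nd <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nd] <- NA_real_
  grid_raster(m,
              xll = if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner,
              yll = if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner,
              cellsize = hdr$cellsize, crs = crs)
}
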