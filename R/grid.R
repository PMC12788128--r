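#' Grid specification for an aligned geographic raster
#'
#' Describes a regular latitude/longitude grid with square cells. Row 0 of an
#' associated value matrix is the northernmost row (ESRI convention); cell
#' membership uses half-open intervals `[west, east) x [south, north)` so a
#' point on a shared boundary belongs to exactly one cell.
#'
#' @param ncols,nrows Positive integer grid dimensions.
#' @param xll,yll Longitude/latitude (decimal degrees) of the lower-left
#'   corner of the grid.
#' @param cellsize Cell edge length in degrees (cells are square).
#' @param nodata Sentinel value written for missing cells in ESRI ASCII output.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(ncols, nrows, xll, yll, cellsize, nodata = -9999) {
  ncols <- as.integer(ncols); nrows <- as.integer(nrows)
  if (is.na(ncols) || is.na(nrows) || ncols < 1L || nrows < 1L)
    stop("ncols and nrows must be integers >= 1", call. = FALSE)
  if (!is.finite(cellsize) || cellsize <= 0)
    stop("cellsize must be > 0", call. = FALSE)
  xur <- xll + ncols * cellsize
  yur <- yll + nrows * cellsize
  if (xll < -180 - 1e-9 || xur > 180 + 1e-9 || yll < -90 - 1e-9 || yur > 90 + 1e-9)
    stop("grid extent falls outside [-180,180] x [-90,90]", call. = FALSE)
  structure(list(ncols = ncols, nrows = nrows, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d cols x %d rows, cellsize %g deg, ll = (%g, %g), nodata %g\n",
              x$ncols, x$nrows, x$cellsize, x$xll, x$yll, x$nodata))
  invisible(x)
}

#' Test whether two grid specifications are aligned
#'
#' Two grids are aligned iff ncols, nrows, xll, yll and cellsize agree within
#' 1e-9 degrees. Downstream operations refuse unaligned inputs rather than
#' resampling silently.
#'
#' @param a,b `grid_spec` objects.
#' @return Logical scalar.
#' @export
specs_aligned <- function(a, b) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  a$ncols == b$ncols && a$nrows == b$nrows &&
    abs(a$xll - b$xll) < 1e-9 && abs(a$yll - b$yll) < 1e-9 &&
    abs(a$cellsize - b$cellsize) < 1e-9
}

#' Raster on a geographic grid
#'
#' A numeric matrix of `nrows x ncols` values bound to a [grid_spec()].
#' Missing (nodata) cells are stored as `NA`; the sentinel in `spec$nodata`
#' only appears in the ESRI ASCII text representation.
#'
#' @param values Numeric matrix, `spec$nrows` rows by `spec$ncols` columns,
#'   row 1 = northernmost row.
#' @param spec A `grid_spec`.
#' @return An object of class `nd_raster`.
#' @export
nd_raster <- function(values, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (nrow(values) != spec$nrows || ncol(values) != spec$ncols)
    stop(sprintf("values are %d x %d but spec declares %d x %d",
                 nrow(values), ncol(values), spec$nrows, spec$ncols),
         call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, spec = spec), class = "nd_raster")
}

#' @export
print.nd_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<nd_raster> %d x %d, %d nodata cells, range [%g, %g]\n",
              nrow(v), ncol(v), sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' Stack of aligned environmental layers
#'
#' @param layers Named list of `nd_raster` objects, all aligned to the same
#'   grid; names are the environmental variable names (e.g. `Bio1`, `elev`).
#' @return An object of class `env_stack` with elements `spec` and `layers`.
#' @export
env_stack <- function(layers) {
  if (length(layers) < 1L) stop("env_stack needs at least one layer", call. = FALSE)
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("layers must have unique non-empty names", call. = FALSE)
  spec <- layers[[1L]]$spec
  for (i in seq_along(layers)) {
    if (!inherits(layers[[i]], "nd_raster"))
      stop("all layers must be nd_raster objects", call. = FALSE)
    if (!specs_aligned(spec, layers[[i]]$spec))
      stop(sprintf("layer '%s' is not aligned to the stack grid", nm[i]),
           call. = FALSE)
  }
  structure(list(spec = spec, layers = layers), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers on %d x %d grid: %s\n",
              length(x$layers), x$spec$nrows, x$spec$ncols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Check that a raster is aligned with a stack's grid
#'
#' @param stack An `env_stack`.
#' @param raster An `nd_raster`.
#' @return Logical scalar: `TRUE` iff the two grid specs are aligned.
#' @export
check_alignment <- function(stack, raster) {
  stopifnot(inherits(stack, "env_stack"), inherits(raster, "nd_raster"))
  specs_aligned(stack$spec, raster$spec)
}

# Row/column of the cell containing each point, half-open convention:
# [west,east) x [south,north). Row 1 is the northern edge. Points outside the
# extent get NA.
cell_index <- function(spec, lon, lat) {
  col <- floor((lon - spec$xll) / spec$cellsize) + 1
  row_from_south <- floor((lat - spec$yll) / spec$cellsize) + 1
  ok <- col >= 1 & col <= spec$ncols & row_from_south >= 1 & row_from_south <= spec$nrows
  row <- spec$nrows - row_from_south + 1
  row[!ok] <- NA_integer_; col[!ok] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

# Cell-center coordinates for given (row, col); row 1 = north.
cell_center <- function(spec, row, col) {
  lon <- spec$xll + (col - 0.5) * spec$cellsize
  lat <- spec$yll + (spec$nrows - row + 0.5) * spec$cellsize
  list(lon = lon, lat = lat)
}

#' Geodesic cell areas by grid row
#'
#' Area of one cell in each grid row on a sphere of radius 6371.0088 km:
#' `R^2 * d_lambda * (sin(phi_N) - sin(phi_S))` with angles in radians.
#' All cells in a row share the same area.
#'
#' @param spec A `grid_spec`.
#' @return Numeric vector of length `nrows` (row 1 = north), in km^2.
#' @export
cell_area_km2 <- function(spec) {
  R <- 6371.0088
  rows <- seq_len(spec$nrows)
  lat_s <- spec$yll + (spec$nrows - rows) * spec$cellsize
  lat_n <- lat_s + spec$cellsize
  R^2 * (spec$cellsize * pi / 180) * (sin(lat_n * pi / 180) - sin(lat_s * pi / 180))
}

# Matrix of per-cell areas (km^2), same shape as raster values.
cell_area_matrix <- function(spec) {
  matrix(rep(cell_area_km2(spec), spec$ncols), nrow = spec$nrows, ncol = spec$ncols)
}
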