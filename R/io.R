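#' Read an ESRI ASCII grid
#'
#' Parses the `.asc` dialect written by MaxEnt and ArcGIS. Header keywords are
#' accepted case-insensitively; both `xllcorner/yllcorner` and
#' `xllcenter/yllcenter` conventions are accepted (centers are converted to
#' corners by subtracting half a cell). Cells equal to the declared
#' `NODATA_value` come back as `NA`.
#'
#' @param path Path to an existing `.asc` file.
#' @return An [nd_raster()].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    if (i > length(lines)) break
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    parts <- strsplit(ln, "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "xllcenter", "yllcenter", "cellsize", "nodata_value")) {
      if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2]))))
        stop(sprintf("malformed ASCII grid header line: '%s'", lines[i]), call. = FALSE)
      hdr[[key]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop(sprintf("ASCII grid header missing: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (is.null(hdr$xllcorner) && is.null(hdr$xllcenter))
    stop("ASCII grid header missing: xllcorner/xllcenter", call. = FALSE)
  if (is.null(hdr$yllcorner) && is.null(hdr$yllcenter))
    stop("ASCII grid header missing: yllcorner/yllcenter", call. = FALSE)
  if (i > length(lines))
    stop("no data section found in ASCII grid", call. = FALSE)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  spec <- grid_spec(hdr$ncols, hdr$nrows, xll, yll, hdr$cellsize, nodata)
  toks <- unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals))
    stop("non-numeric cell value in ASCII grid data section", call. = FALSE)
  if (length(vals) != spec$nrows * spec$ncols)
    stop(sprintf("ASCII grid declares %d cells but contains %d values",
                 spec$nrows * spec$ncols, length(vals)), call. = FALSE)
  m <- matrix(vals, nrow = spec$nrows, ncol = spec$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  nd_raster(m, spec)
}

#' Write an ESRI ASCII grid
#'
#' Writes the `xllcorner` dialect; `NA` cells are written as the spec's nodata
#' sentinel. Values round-trip through [read_ascii_grid()] at the declared
#' precision.
#'
#' @param raster An [nd_raster()].
#' @param path Output path.
#' @param precision Number of decimal digits for cell values (default 6).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path, precision = 6) {
  stopifnot(inherits(raster, "nd_raster"))
  s <- raster$spec
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot open '%s' for writing", path), call. = FALSE))
  on.exit(close(con))
  num <- function(x) formatC(x, format = "g", digits = 15)
  writeLines(c(paste("ncols", s$ncols),
               paste("nrows", s$nrows),
               paste("xllcorner", num(s$xll)),
               paste("yllcorner", num(s$yll)),
               paste("cellsize", num(s$cellsize)),
               paste("NODATA_value", num(s$nodata))), con)
  v <- raster$values
  for (r in seq_len(s$nrows)) {
    row <- v[r, ]
    out <- formatC(row, format = "f", digits = precision)
    out[is.na(row)] <- num(s$nodata)
    writeLines(paste(out, collapse = " "), con)
  }
  invisible(path)
}

#' Read occurrence records from delimited text
#'
#' Expects a header row with at least `species`, `lon` and `lat` columns
#' (`elevation` and `source` are optional). Record order is preserved;
#' duplicated rows are kept (removing within-cell duplicates is the job of
#' [thin_occurrences()]).
#'
#' @param path Path to a CSV file.
#' @return A data frame of class `occurrence_set` with columns `species`,
#'   `lon`, `lat`, `elevation`, `source`.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("species", "lon", "lat"), names(df))
  if (length(miss))
    stop(sprintf("occurrence file missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  bad_num <- which(is.na(lon) | is.na(lat))
  if (length(bad_num))
    stop(sprintf("non-numeric coordinates at row(s): %s",
                 paste(bad_num, collapse = ", ")), call. = FALSE)
  bad_rng <- which(lon < -180 | lon > 180 | lat < -90 | lat > 90)
  if (length(bad_rng))
    stop(sprintf("coordinates out of range at row(s): %s",
                 paste(bad_rng, collapse = ", ")), call. = FALSE)
  if (any(!nzchar(df$species)))
    stop("empty species names are not allowed", call. = FALSE)
  occurrence_set(df$species, lon, lat,
                 elevation = if ("elevation" %in% names(df))
                   suppressWarnings(as.numeric(df$elevation)) else NA_real_,
                 source = if ("source" %in% names(df))
                   as.character(df$source) else NA_character_)
}

#' Construct an occurrence set
#'
#' @param species Character vector of species names (non-empty).
#' @param lon,lat Numeric coordinate vectors in decimal degrees.
#' @param elevation Optional numeric elevations (m).
#' @param source Optional character record sources.
#' @return A data frame with class `occurrence_set`.
#' @export
occurrence_set <- function(species, lon, lat, elevation = NA_real_,
                           source = NA_character_) {
  if (any(lon < -180 | lon > 180, na.rm = TRUE) ||
      any(lat < -90 | lat > 90, na.rm = TRUE))
    stop("coordinates out of range", call. = FALSE)
  if (any(!nzchar(species))) stop("species names must be non-empty", call. = FALSE)
  df <- data.frame(species = as.character(species), lon = lon, lat = lat,
                   elevation = elevation, source = source,
                   stringsAsFactors = FALSE)
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' Write an occurrence set to CSV
#'
#' @param occ An `occurrence_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}
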