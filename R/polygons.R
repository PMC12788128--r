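#' Polygon set in geographic coordinates
#'
#' A lightweight container for protected-area boundaries: a list of polygons,
#' each a list of rings, each ring a two-column (lon, lat) matrix. The first
#' ring is the outer boundary; additional rings are holes. Point-in-polygon
#' queries use the even-odd rule, so holes need no special casing.
#'
#' @param polygons List of polygons; each polygon is either a two-column
#'   matrix (single ring) or a list of two-column matrices (rings).
#' @return An object of class `polygon_set`.
#' @export
polygon_set <- function(polygons = list()) {
  polys <- lapply(polygons, function(p) {
    if (is.matrix(p)) p <- list(p)
    lapply(p, function(ring) {
      ring <- as.matrix(ring)
      if (ncol(ring) != 2 || nrow(ring) < 3)
        stop("each ring must be a matrix with >= 3 (lon, lat) rows", call. = FALSE)
      storage.mode(ring) <- "double"
      ring
    })
  })
  structure(list(polygons = polys), class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("<polygon_set> %d polygon(s)\n", length(x$polygons)))
  invisible(x)
}

#' Test points against a polygon set
#'
#' Even-odd ray-casting over all rings of all polygons. Points exactly on an
#' edge are resolved by the half-open crossing rule (deterministic, but such
#' points should not be relied on).
#'
#' @param polys A [polygon_set()].
#' @param lon,lat Numeric coordinate vectors.
#' @return Logical vector: is each point inside any polygon?
#' @export
points_in_polygons <- function(polys, lon, lat) {
  stopifnot(inherits(polys, "polygon_set"))
  inside <- rep(FALSE, length(lon))
  for (poly in polys$polygons) {
    crossings <- rep(0L, length(lon))
    for (ring in poly) {
      x <- ring[, 1]; y <- ring[, 2]
      n <- length(x)
      if (x[1] == x[n] && y[1] == y[n]) n <- n - 1L  # drop repeated closing vertex
      j <- n
      for (i in seq_len(n)) {
        cross <- ((y[i] > lat) != (y[j] > lat)) &
          (lon < (x[j] - x[i]) * (lat - y[i]) / (y[j] - y[i]) + x[i])
        crossings <- crossings + as.integer(cross)
        j <- i
      }
    }
    inside <- inside | (crossings %% 2L == 1L)
  }
  inside
}

#' Read polygons from GeoJSON
#'
#' Accepts a FeatureCollection, a single Feature, or a bare geometry of type
#' Polygon or MultiPolygon.
#'
#' @param path Path to a GeoJSON file.
#' @return A [polygon_set()].
#' @export
read_geojson_polygons <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  geoms <- switch(g$type %||% "",
                  FeatureCollection = lapply(g$features, function(f) f$geometry),
                  Feature = list(g$geometry),
                  Polygon = , MultiPolygon = list(g),
                  stop("unsupported GeoJSON type", call. = FALSE))
  polys <- list()
  for (geom in geoms) {
    ring_to_mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    if (geom$type == "Polygon") {
      polys[[length(polys) + 1L]] <- lapply(geom$coordinates, ring_to_mat)
    } else if (geom$type == "MultiPolygon") {
      for (p in geom$coordinates)
        polys[[length(polys) + 1L]] <- lapply(p, ring_to_mat)
    } else stop(sprintf("unsupported geometry type '%s'", geom$type), call. = FALSE)
  }
  polygon_set(polys)
}

#' Write a polygon set to GeoJSON
#'
#' @param polys A [polygon_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(polys, path) {
  stopifnot(inherits(polys, "polygon_set"))
  feats <- lapply(polys$polygons, function(poly) {
    coords <- lapply(poly, function(ring) {
      if (!all(ring[1, ] == ring[nrow(ring), ]))
        ring <- rbind(ring, ring[1, ])
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
    })
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
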