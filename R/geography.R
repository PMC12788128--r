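#' Centroid of highly suitable habitat
#'
#' Area-weighted mean of the cell-center coordinates of high-class cells
#' (weights = geodesic cell areas). Longitudes are averaged arithmetically;
#' the supported extents do not span the antimeridian.
#'
#' @param c A `classified_raster`.
#' @return Named numeric vector `c(lon, lat)`.
#' @export
centroid_high <- function(c) {
  stopifnot(inherits(c, "classified_raster"))
  v <- c$values
  idx <- which(!is.na(v) & v == 3)
  if (!length(idx)) stop("no highly suitable cells", call. = FALSE)
  spec <- c$spec
  row <- ((idx - 1) %% spec$nrows) + 1
  col <- ((idx - 1) %/% spec$nrows) + 1
  ctr <- cell_center(spec, row, col)
  w <- cell_area_matrix(spec)[idx]
  c(lon = sum(w * ctr$lon) / sum(w), lat = sum(w * ctr$lat) / sum(w))
}

#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param a,b Numeric `(lon, lat)` pairs in decimal degrees.
#' @return Distance in km.
#' @export
haversine_km <- function(a, b) {
  R <- 6371.0088
  to_rad <- pi / 180
  dlat <- (b[2] - a[2]) * to_rad
  dlon <- (b[1] - a[1]) * to_rad
  h <- sin(dlat / 2)^2 + cos(a[2] * to_rad) * cos(b[2] * to_rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(h)))
}

#' Centroid migration track across periods
#'
#' Computes the high-suitability centroid for each period of a scenario and
#' the consecutive great-circle displacements (one fewer than the number of
#' periods; with four periods this gives the n = 3 per-scenario distances used
#' in the between-scenario test).
#'
#' @param classified_list Named list of `classified_raster`s in period order.
#' @param scenario Label stored with the track.
#' @return Object of class `centroid_track`: data frame `track` (`period`,
#'   `lon`, `lat`) and numeric `distances_km`.
#' @export
centroid_track <- function(classified_list, scenario = "scenario") {
  cents <- t(vapply(classified_list, centroid_high, numeric(2)))
  tr <- data.frame(period = names(classified_list),
                   lon = cents[, 1], lat = cents[, 2], row.names = NULL)
  d <- vapply(seq_len(nrow(tr) - 1), function(i)
    haversine_km(c(tr$lon[i], tr$lat[i]), c(tr$lon[i + 1], tr$lat[i + 1])),
    numeric(1))
  structure(list(scenario = scenario, track = tr, distances_km = d),
            class = "centroid_track")
}

#' Kruskal-Wallis rank test
#'
#' Mid-ranks for ties; `H = 12/(N(N+1)) * sum n_i R_i^2 - 3(N+1)` divided by
#' the tie-correction factor `1 - sum(t^3 - t)/(N^3 - N)`; p-value from the
#' upper tail of chi-square with `k - 1` degrees of freedom. All-tied input
#' returns `H = 0`, `p = 1`.
#'
#' @param groups List (>= 2) of non-empty numeric vectors.
#' @return Object of class `kw_result`: `H`, `df`, `p_value`, `mean_ranks`,
#'   `tie_correction`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, numeric(1)) == 0))
    stop("empty group", call. = FALSE)
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, numeric(1)))
  N <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  n_i <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(n_i * mean_ranks^2) - 3 * (N + 1)
  t_counts <- table(x)
  C <- 1 - sum(t_counts^3 - t_counts) / (N^3 - N)
  if (C <= 0) { H <- 0; p <- 1 }  # all observations tied
  else {
    H <- H / C
    p <- stats::pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  }
  structure(list(H = H, df = length(groups) - 1, p_value = p,
                 mean_ranks = as.numeric(mean_ranks),
                 tie_correction = C, n = as.integer(n_i)),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("<kw_result> H = %.2f, df = %d, p = %.3f (mean ranks: %s)\n",
              x$H, x$df, x$p_value,
              paste(sprintf("%.2f", x$mean_ranks), collapse = ", ")))
  invisible(x)
}

#' Gap-result bookkeeping from priority and covered areas
#'
#' @param priority_area,covered_area Areas in 10^4 km^2;
#'   `covered_area <= priority_area`.
#' @return Object of class `gap_result`: the two areas plus `coverage_pct`
#'   and `gap_pct` (summing to 100).
#' @export
gap_result <- function(priority_area, covered_area) {
  if (priority_area <= 0) stop("priority area must be > 0", call. = FALSE)
  if (covered_area > priority_area + 1e-9)
    stop("covered area exceeds priority area", call. = FALSE)
  cov <- 100 * covered_area / priority_area
  structure(list(priority_area = priority_area, covered_area = covered_area,
                 coverage_pct = cov, gap_pct = 100 - cov),
            class = "gap_result")
}

#' @export
print.gap_result <- function(x, ...) {
  cat(sprintf("<gap_result> priority %.2f, covered %.2f (10^4 km^2): coverage %.2f%%, gap %.2f%%\n",
              x$priority_area, x$covered_area, x$coverage_pct, x$gap_pct))
  invisible(x)
}

#' Protected-area gap analysis
#'
#' Priority conservation area = moderate + high suitability classes. A
#' priority cell counts as covered iff its center falls inside any protected
#' polygon; areas are geodesic, in 10^4 km^2.
#'
#' @param current A `classified_raster` for the reference period.
#' @param protected A [polygon_set()] in the raster's geographic coordinates.
#' @return A [gap_result()].
#' @export
gap_analysis <- function(current, protected) {
  stopifnot(inherits(current, "classified_raster"))
  v <- current$values
  idx <- which(!is.na(v) & v >= 2)
  if (!length(idx)) stop("priority mask is empty", call. = FALSE)
  spec <- current$spec
  row <- ((idx - 1) %% spec$nrows) + 1
  col <- ((idx - 1) %/% spec$nrows) + 1
  ctr <- cell_center(spec, row, col)
  area <- cell_area_matrix(spec)[idx] / 1e4
  covered <- if (length(protected$polygons))
    points_in_polygons(protected, ctr$lon, ctr$lat) else rep(FALSE, length(idx))
  gap_result(sum(area), sum(area[covered]))
}

#' Priority area and coverage across scenario periods
#'
#' Classifies each period raster and runs [gap_analysis()] per
#' (scenario, period).
#'
#' @param scen A `scenario_set`.
#' @param protected A [polygon_set()].
#' @param thresholds Class thresholds.
#' @return Data frame: `scenario`, `period`, `priority_area`, `covered_area`,
#'   `coverage_pct`, `gap_pct`.
#' @export
scenario_gap_series <- function(scen, protected,
                                thresholds = c(poor = 0.1, moderate = 0.3,
                                               high = 0.5)) {
  out <- NULL
  for (sc in scen$scenarios) for (p in names(scen$rasters[[sc]])) {
    g <- gap_analysis(classify_suitability(scen$rasters[[sc]][[p]],
                                           thresholds = thresholds), protected)
    out <- rbind(out, data.frame(scenario = sc, period = p,
                                 priority_area = g$priority_area,
                                 covered_area = g$covered_area,
                                 coverage_pct = g$coverage_pct,
                                 gap_pct = g$gap_pct))
  }
  out
}
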