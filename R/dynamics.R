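#' Round half away from zero
#'
#' Reported percentages in the dynamics tables use half-away-from-zero
#' rounding (the convention of the tabulated results), not R's banker's
#' rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Classify a suitability surface into four habitat classes
#'
#' Thresholds on the logistic suitability scale: unsuitable `p < 0.1` (0),
#' poor `0.1 <= p < 0.3` (1), moderate `0.3 <= p < 0.5` (2), high
#' `0.5 <= p <= 1` (3). Lower bounds inclusive, upper exclusive; the high
#' class includes 1.0. Nodata cells stay `NA`.
#'
#' @param p An [nd_raster()] with values in `[0, 1]` at valid cells.
#' @param thresholds Lower bounds of the three suitable classes.
#' @return An `nd_raster` of class codes 0-3 with class
#'   `c("classified_raster", "nd_raster")` and attribute `"thresholds"`.
#' @export
classify_suitability <- function(p, thresholds = c(poor = 0.1, moderate = 0.3,
                                                   high = 0.5)) {
  stopifnot(inherits(p, "nd_raster"))
  v <- p$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  cls <- matrix(0, nrow(v), ncol(v))
  cls[v >= thresholds[["poor"]]] <- 1
  cls[v >= thresholds[["moderate"]]] <- 2
  cls[v >= thresholds[["high"]]] <- 3
  cls[is.na(v)] <- NA_real_
  out <- nd_raster(cls, p$spec)
  class(out) <- c("classified_raster", class(out))
  attr(out, "thresholds") <- thresholds
  out
}

#' Per-class geodesic areas
#'
#' Sums geodesic cell areas (sphere of radius 6371.0088 km) within each
#' suitability class, reported in 10^4 km^2.
#'
#' @param c A `classified_raster` from [classify_suitability()].
#' @return Named numeric vector `unsuitable`, `poor`, `moderate`, `high`,
#'   `total_suitable` (poor + moderate + high), in 10^4 km^2.
#' @export
area_by_class <- function(c) {
  stopifnot(inherits(c, "classified_raster"))
  area <- cell_area_matrix(c$spec) / 1e4
  v <- c$values
  by_cls <- vapply(0:3, function(k) sum(area[!is.na(v) & v == k]), numeric(1))
  stats::setNames(c(by_cls, sum(by_cls[2:4])),
                  c("unsuitable", "poor", "moderate", "high", "total_suitable"))
}

#' Transition accounting between two classified periods
#'
#' "Suitable" is the union of the poor, moderate and high classes
#' (`class >= 1`, i.e. `p >= 0.1`). Returns the five areas of the dynamics
#' framework plus the full 4x4 class-to-class flow matrix (initial class in
#' rows, final class in columns), all in 10^4 km^2. Only cells valid in both
#' periods contribute.
#'
#' @param c1,c2 `classified_raster`s on aligned grids with equal thresholds.
#' @return Object of class `transition_summary` with fields `a_initial`,
#'   `a_final`, `a_expansion`, `a_contraction`, `a_stable`, `flow`.
#' @export
transition_summary <- function(c1, c2) {
  stopifnot(inherits(c1, "classified_raster"), inherits(c2, "classified_raster"))
  if (!specs_aligned(c1$spec, c2$spec))
    stop("classified rasters are not aligned", call. = FALSE)
  if (!isTRUE(all.equal(attr(c1, "thresholds"), attr(c2, "thresholds"))))
    stop("classified rasters use different thresholds", call. = FALSE)
  area <- cell_area_matrix(c1$spec) / 1e4
  v1 <- c1$values; v2 <- c2$values
  ok <- !is.na(v1) & !is.na(v2)
  flow <- matrix(0, 4, 4, dimnames = list(
    initial = c("unsuitable", "poor", "moderate", "high"),
    final = c("unsuitable", "poor", "moderate", "high")))
  for (i in 0:3) for (j in 0:3)
    flow[i + 1, j + 1] <- sum(area[ok & v1 == i & v2 == j])
  s1 <- ok & v1 >= 1; s2 <- ok & v2 >= 1
  structure(list(
    a_initial = sum(area[s1]),
    a_final = sum(area[s2]),
    a_expansion = sum(area[!s1 & s2 & ok]),
    a_contraction = sum(area[s1 & !s2]),
    a_stable = sum(area[s1 & s2]),
    flow = flow), class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf(paste0("<transition_summary> (10^4 km^2) initial %.2f, final %.2f,",
                     " expansion %.2f, contraction %.2f, stable %.2f\n"),
              x$a_initial, x$a_final, x$a_expansion, x$a_contraction, x$a_stable))
  invisible(x)
}

#' Relative change rate of suitable area
#'
#' `RCR = (A_final - A_initial) / A_initial * 100` (percent).
#'
#' @param a_initial,a_final Suitable areas in any common unit; `a_initial > 0`.
#' @return RCR in percent (unrounded).
#' @export
relative_change_rate <- function(a_initial, a_final) {
  if (any(a_initial <= 0)) stop("a_initial must be > 0", call. = FALSE)
  (a_final - a_initial) / a_initial * 100
}

#' Habitat-dynamics indicators from a transition summary
#'
#' * RCR (%): `(A_final - A_initial) / A_initial * 100` — magnitude of change.
#' * CI (%): `(A_expansion + A_contraction) / A_initial * 100` — activity level.
#' * SI (%): `A_stable / A_initial * 100` — persistence of the core area.
#' * SDR: `min(A_expansion, A_contraction) / (A_expansion + A_contraction)`,
#'   in `[0, 0.5]`, defined as 0 when there is no change — spatial
#'   reorganization (0.5 = pure displacement, equal gain and loss).
#'
#' Values are returned at full precision; use [round_half_away()] (or the
#' print method) for the 2-decimal reporting convention.
#'
#' @param ts A [transition_summary()] (or any list with the five areas).
#' @return Object of class `dynamics_indicators`: `rcr`, `ci`, `si`, `sdr`.
#' @export
indicators <- function(ts) {
  if (ts$a_initial <= 0)
    stop("indicators undefined: initial suitable area is zero", call. = FALSE)
  chg <- ts$a_expansion + ts$a_contraction
  structure(list(
    rcr = relative_change_rate(ts$a_initial, ts$a_final),
    ci = chg / ts$a_initial * 100,
    si = ts$a_stable / ts$a_initial * 100,
    sdr = if (chg == 0) 0 else min(ts$a_expansion, ts$a_contraction) / chg),
    class = "dynamics_indicators")
}

#' @export
print.dynamics_indicators <- function(x, ...) {
  cat(sprintf("<dynamics_indicators> RCR %.2f%%, CI %.2f%%, SI %.2f%%, SDR %.2f\n",
              round_half_away(x$rcr), round_half_away(x$ci),
              round_half_away(x$si), round_half_away(x$sdr)))
  invisible(x)
}

#' Period mean of a reported indicator
#'
#' The tabulated period means are arithmetic means of the per-transition
#' values *after* each is rounded to two decimals (half away from zero) — the
#' arithmetic of the reported tables — and the mean itself is reported to the
#' same precision.
#'
#' @param values Numeric vector of per-transition indicator values.
#' @return Scalar mean, rounded to 2 decimals.
#' @export
period_mean <- function(values) {
  if (!length(values)) stop("period_mean needs at least one value", call. = FALSE)
  round_half_away(mean(round_half_away(values, 2)), 2)
}

#' Dynamics table across a scenario set
#'
#' Classifies every period raster, computes consecutive-period transitions and
#' indicators per scenario, and appends a period-mean row per scenario
#' (rounded reporting convention).
#'
#' @param scen A `scenario_set` (see [make_scenario_set()]) or an equivalent
#'   list with `scenarios`, `periods`, `rasters`.
#' @param thresholds Class thresholds passed to [classify_suitability()].
#' @return Data frame with columns `scenario`, `transition`, `rcr`, `ci`,
#'   `si`, `sdr` (full precision for transitions; period-mean rows follow the
#'   rounded convention).
#' @export
dynamics_table <- function(scen, thresholds = c(poor = 0.1, moderate = 0.3,
                                                high = 0.5)) {
  out <- NULL
  for (sc in scen$scenarios) {
    periods <- names(scen$rasters[[sc]])
    cls <- lapply(scen$rasters[[sc]], classify_suitability, thresholds = thresholds)
    per_ind <- NULL
    for (k in seq_len(length(periods) - 1)) {
      ind <- indicators(transition_summary(cls[[k]], cls[[k + 1]]))
      per_ind <- rbind(per_ind, data.frame(
        scenario = sc, transition = paste(periods[k], periods[k + 1], sep = "-"),
        rcr = ind$rcr, ci = ind$ci, si = ind$si, sdr = ind$sdr))
    }
    out <- rbind(out, per_ind, data.frame(
      scenario = sc, transition = "period_mean",
      rcr = period_mean(per_ind$rcr), ci = period_mean(per_ind$ci),
      si = period_mean(per_ind$si), sdr = period_mean(per_ind$sdr)))
  }
  out
}
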