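#' Default desk-scale grid for synthetic data
#'
#' 100 x 120 cells at 0.05 degrees (~5 km at these latitudes), centred on a
#' subtropical extent, mirroring the working resolution of 2.5-arc-minute
#' bioclim layers.
#'
#' @param nodata Nodata sentinel.
#' @return A [grid_spec()].
#' @export
default_synth_spec <- function(nodata = -9999) {
  grid_spec(ncols = 120, nrows = 100, xll = 105, yll = 25, cellsize = 0.05,
            nodata = nodata)
}

# Smooth standardized random field: white noise low-pass filtered with a
# moving-average kernel (width in cells), then z-scored over all cells.
smooth_field <- function(nrows, ncols, width = 5) {
  z <- matrix(stats::rnorm(nrows * ncols), nrows, ncols)
  k <- rep(1 / width, width)
  pad <- function(m, n) m[c(rep(1, n), seq_len(nrow(m)), rep(nrow(m), n)), ]
  half <- (width - 1) %/% 2
  sm_rows <- apply(pad(z, half), 2, function(col) stats::filter(col, k, sides = 2))
  sm_rows <- sm_rows[(half + 1):(half + nrows), , drop = FALSE]
  sm <- t(apply(pad(t(sm_rows), half), 2,
                function(row) stats::filter(row, k, sides = 2)))
  sm <- sm[, (half + 1):(half + ncols), drop = FALSE]
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate a synthetic environmental stack
#'
#' Layers are smooth random fields (low-pass-filtered white noise, kernel
#' width 5 cells) rescaled to plausible variable ranges. Requested pairwise
#' correlations are imposed exactly in the empirical sense: the second member
#' of each pair is rebuilt as `r * z_i + sqrt(1 - r^2) * e` where `e` is the
#' empirically orthogonalized residual, so the realized Pearson r over cells
#' equals the target up to floating-point error.
#'
#' @param seed Integer seed; the generator is a pure function of it.
#' @param spec A [grid_spec()]; default [default_synth_spec()].
#' @param n_vars Number of layers (>= 2), named `Bio1..Bio<n>`.
#' @param corr_pairs Optional list of `list(i, j, r)` triples requesting
#'   Pearson correlation `r` between layers `i` and `j`. A layer may appear as
#'   the adjusted member (`j`) of at most one pair.
#' @return An [env_stack()].
#' @export
make_env_stack <- function(seed, spec = default_synth_spec(), n_vars = 6,
                           corr_pairs = list()) {
  if (n_vars < 2) stop("n_vars must be >= 2", call. = FALSE)
  for (p in corr_pairs) {
    if (length(p) != 3 || abs(p[[3]]) > 1)
      stop("each corr_pair must be list(i, j, r) with |r| <= 1", call. = FALSE)
    if (p[[1]] == p[[2]])
      stop("corr_pair cannot pair a variable with itself", call. = FALSE)
  }
  adj <- vapply(corr_pairs, function(p) p[[2]], numeric(1))
  if (anyDuplicated(adj))
    stop("contradictory correlation requests: a variable may be adjusted by at most one pair",
         call. = FALSE)
  set.seed(seed)
  fields <- lapply(seq_len(n_vars), function(i) smooth_field(spec$nrows, spec$ncols))
  for (p in corr_pairs) {
    i <- p[[1]]; j <- p[[2]]; r <- p[[3]]
    zi <- fields[[i]]; zj <- fields[[j]]
    zi <- (zi - mean(zi)) / stats::sd(zi)
    resid <- zj - stats::cov(as.vector(zj), as.vector(zi)) /
      stats::var(as.vector(zi)) * zi
    resid <- (resid - mean(resid)) / stats::sd(resid)
    fields[[j]] <- r * zi + sqrt(1 - r^2) * resid
  }
  # rescale to plausible ranges: temperature-like for odd, precip-like for even
  layers <- vector("list", n_vars)
  for (i in seq_len(n_vars)) {
    f <- fields[[i]]
    f <- if (i %% 2 == 1) 15 + 6 * f else 1200 + 400 * f
    layers[[i]] <- nd_raster(f, spec)
  }
  names(layers) <- paste0("Bio", seq_len(n_vars))
  env_stack(layers)
}

#' Ground-truth species-environment relationship
#'
#' Suitability is the inverse logit of a linear-quadratic score of the named
#' environmental layers (plus optional Gaussian noise on the score), so it is
#' always in (0, 1).
#'
#' @param coefficients Named list: variable name -> `c(linear, quadratic)`
#'   weights applied to the z-scored layer.
#' @param intercept Scalar intercept of the score.
#' @param noise_sd Standard deviation of score noise (>= 0).
#' @return An object of class `truth_model`.
#' @export
truth_model <- function(coefficients, intercept = 0, noise_sd = 0) {
  if (length(coefficients) == 0 ||
      all(vapply(coefficients, function(w) all(w == 0), logical(1))))
    stop("truth_model needs at least one nonzero weight", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(coefficients = coefficients, intercept = intercept,
                 noise_sd = noise_sd), class = "truth_model")
}

#' Evaluate a truth model over a stack
#'
#' @param truth A [truth_model()].
#' @param stack An [env_stack()] containing all variables named in `truth`.
#' @return An [nd_raster()] of suitabilities in (0, 1); nodata propagates.
#' @export
truth_suitability <- function(truth, stack) {
  miss <- setdiff(names(truth$coefficients), names(stack$layers))
  if (length(miss))
    stop(sprintf("stack lacks truth variables: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  score <- matrix(truth$intercept, stack$spec$nrows, stack$spec$ncols)
  for (v in names(truth$coefficients)) {
    x <- stack$layers[[v]]$values
    z <- (x - mean(x, na.rm = TRUE)) / stats::sd(as.vector(x), na.rm = TRUE)
    w <- truth$coefficients[[v]]
    score <- score + w[1] * z + if (length(w) > 1) w[2] * z^2 else 0
  }
  if (truth$noise_sd > 0)
    score <- score + matrix(stats::rnorm(length(score), 0, truth$noise_sd),
                            nrow(score), ncol(score))
  nd_raster(stats::plogis(score), stack$spec)
}

#' Sample occurrence records from a known suitability surface
#'
#' Cells are drawn with probability proportional to truth suitability; a
#' `duplicate_rate` fraction of the records are re-draws inside
#' already-sampled cells. Every point is jittered uniformly within its cell,
#' so de-duplication requires grid-cell thinning, not coordinate matching.
#'
#' @param truth A [truth_model()].
#' @param stack An [env_stack()].
#' @param n Total number of records (>= 1).
#' @param duplicate_rate Fraction in `[0, 1)` of records that duplicate an
#'   already-occupied cell.
#' @param seed Integer seed.
#' @param species Species label for the records.
#' @return An `occurrence_set`. The attribute `"cells"` holds each record's
#'   (row, col) cell, for ground-truth bookkeeping.
#' @export
sample_occurrences <- function(truth, stack, n, duplicate_rate = 0, seed = 1,
                               species = "synthetic_sp") {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (duplicate_rate < 0 || duplicate_rate >= 1)
    stop("duplicate_rate must be in [0, 1)", call. = FALSE)
  set.seed(seed)
  suit <- truth_suitability(truth, stack)$values
  ok <- which(!is.na(suit))
  if (!length(ok)) stop("stack has no valid cells", call. = FALSE)
  n_dup <- round(n * duplicate_rate)
  n_base <- n - n_dup
  base_cells <- sample(ok, n_base, replace = TRUE, prob = suit[ok])
  dup_cells <- if (n_dup > 0) sample(base_cells, n_dup, replace = TRUE) else integer(0)
  cells <- c(base_cells, dup_cells)
  spec <- stack$spec
  row <- ((cells - 1) %% spec$nrows) + 1
  col <- ((cells - 1) %/% spec$nrows) + 1
  ctr <- cell_center(spec, row, col)
  jit <- spec$cellsize * 0.49
  lon <- ctr$lon + stats::runif(length(cells), -jit, jit)
  lat <- ctr$lat + stats::runif(length(cells), -jit, jit)
  occ <- occurrence_set(rep(species, length(cells)), lon, lat)
  attr(occ, "cells") <- data.frame(row = row, col = col)
  occ
}

#' Construct multi-period suitability scenarios with known dynamics
#'
#' Starting from a base suitability raster, builds per-scenario period
#' sequences in which a planned number of cells cross the 0.1
#' suitable/unsuitable boundary in each direction per transition. Cells are
#' flipped at the frontier of the current suitable patch (seeded, one cell at
#' a time), and expansion/contraction sets within a transition are disjoint,
#' so `A_final = A_initial + A_expansion - A_contraction` holds exactly.
#'
#' @param base An [nd_raster()] of suitabilities in `[0, 1]`; "current" period.
#' @param plan Named list: scenario -> list of per-period
#'   `list(period, expand, contract)` entries (cell counts), applied in order.
#' @param seed Integer seed.
#' @return An object of class `scenario_set`: `periods`, `scenarios`,
#'   `rasters[[scenario]][[period]]`, and `truth`, a data frame of realized
#'   expansion/contraction areas (10^4 km^2) per transition.
#' @export
make_scenario_set <- function(base, plan, seed = 1) {
  stopifnot(inherits(base, "nd_raster"))
  set.seed(seed)
  spec <- base$spec
  area <- cell_area_matrix(spec) / 1e4
  scen_names <- names(plan)
  periods <- unique(unlist(lapply(plan, function(p)
    vapply(p, function(e) e$period, character(1)))))
  rasters <- list()
  truth <- NULL
  for (sc in scen_names) {
    cur <- base
    rasters[[sc]] <- list(current = base)
    for (step in plan[[sc]]) {
      nxt <- flip_frontier_cells(cur, step$expand, step$contract)
      rasters[[sc]][[step$period]] <- nxt$raster
      truth <- rbind(truth, data.frame(
        scenario = sc, period = step$period,
        a_expansion = sum(area[nxt$expanded]),
        a_contraction = sum(area[nxt$contracted])))
      cur <- nxt$raster
    }
  }
  structure(list(periods = c("current", periods), scenarios = scen_names,
                 rasters = rasters, truth = truth),
            class = "scenario_set")
}

# Flip `expand` unsuitable cells to suitable (p = 0.2) and `contract` suitable
# cells to unsuitable (p = 0.05), one frontier cell at a time. Expansion picks
# unsuitable cells 4-adjacent to the suitable patch; contraction picks suitable
# cells 4-adjacent to unsuitable area; the two sets stay disjoint.
flip_frontier_cells <- function(raster, expand, contract) {
  v <- raster$values
  suit0 <- !is.na(v) & v >= 0.1
  suit <- suit0
  nr <- nrow(v); nc <- ncol(v)
  neighbours <- function(idx) {
    r <- ((idx - 1) %% nr) + 1; c <- ((idx - 1) %/% nr) + 1
    nb <- c(if (r > 1) idx - 1, if (r < nr) idx + 1,
            if (c > 1) idx - nr, if (c < nc) idx + nr)
    nb
  }
  pick_frontier <- function(target_state, exclude) {
    # cells with state !target_state adjacent to a target_state cell
    cand <- which(!is.na(v) & (suit != target_state))
    cand <- setdiff(cand, exclude)
    front <- cand[vapply(cand, function(i) any(suit[neighbours(i)] == target_state),
                         logical(1))]
    if (length(front)) front else cand
  }
  expanded <- integer(0); contracted <- integer(0)
  for (k in seq_len(expand)) {
    cand <- setdiff(pick_frontier(TRUE, contracted), which(suit0))
    if (!length(cand)) stop("requested expansion exceeds available cells", call. = FALSE)
    i <- if (length(cand) == 1) cand else sample(cand, 1)
    suit[i] <- TRUE; expanded <- c(expanded, i)
  }
  for (k in seq_len(contract)) {
    cand <- intersect(setdiff(pick_frontier(FALSE, expanded), expanded),
                      which(suit0))
    if (!length(cand)) stop("requested contraction exceeds available cells", call. = FALSE)
    i <- if (length(cand) == 1) cand else sample(cand, 1)
    suit[i] <- FALSE; contracted <- c(contracted, i)
  }
  v[expanded] <- 0.2
  v[contracted] <- 0.05
  list(raster = nd_raster(v, raster$spec), expanded = expanded,
       contracted = contracted)
}

#' Two-species occurrence clouds with controlled niche separation
#'
#' Builds a two-layer environmental stack whose layers vary linearly with
#' longitude and latitude, and places each species' points so their extracted
#' environmental values follow bivariate normal clouds whose means are
#' `separation` pooled standard deviations apart. `separation = 0` gives
#' identical niches; large values give disjoint niches.
#'
#' @param separation Distance between niche centroids in pooled-SD units (>= 0).
#' @param n_per_species Points per species (>= 5; kernel density needs support).
#' @param seed Integer seed.
#' @param spec Grid to build the stack on.
#' @return List with `occ` (an `occurrence_set` with species `spA`, `spB`) and
#'   `stack` (an [env_stack()] with layers `env1`, `env2`).
#' @export
make_species_pair <- function(separation, n_per_species, seed = 1,
                              spec = default_synth_spec()) {
  if (n_per_species < 5)
    stop("n_per_species must be >= 5 for kernel density estimation", call. = FALSE)
  if (separation < 0) stop("separation must be >= 0", call. = FALSE)
  set.seed(seed)
  # env1 increases with lon, env2 with lat; unit chosen so +-(sep/2 + 5 SD)
  # stays inside the extent
  lon_range <- spec$ncols * spec$cellsize
  lat_range <- spec$nrows * spec$cellsize
  units_needed <- separation + 10
  sd_lon <- lon_range / units_needed
  sd_lat <- lat_range / units_needed
  cx <- spec$xll + lon_range / 2
  cy <- spec$yll + lat_range / 2
  draw <- function(mu_units, n) {
    lon <- cx + (mu_units + stats::rnorm(n)) * sd_lon
    lat <- cy + stats::rnorm(n) * sd_lat
    lon <- pmin(pmax(lon, spec$xll + spec$cellsize / 2),
                spec$xll + lon_range - spec$cellsize / 2)
    lat <- pmin(pmax(lat, spec$yll + spec$cellsize / 2),
                spec$yll + lat_range - spec$cellsize / 2)
    cbind(lon, lat)
  }
  a <- draw(-separation / 2, n_per_species)
  b <- draw(+separation / 2, n_per_species)
  occ <- occurrence_set(c(rep("spA", n_per_species), rep("spB", n_per_species)),
                        c(a[, 1], b[, 1]), c(a[, 2], b[, 2]))
  mk_linear <- function(along_lon) {
    ctr <- cell_center(spec, rep(seq_len(spec$nrows), spec$ncols),
                       rep(seq_len(spec$ncols), each = spec$nrows))
    val <- if (along_lon) ctr$lon else ctr$lat
    nd_raster(matrix(val, spec$nrows, spec$ncols), spec)
  }
  stack <- env_stack(list(env1 = mk_linear(TRUE), env2 = mk_linear(FALSE)))
  list(occ = occ, stack = stack)
}

#' Construct protected-area polygons with known coverage
#'
#' Selects priority cells (seeded order) until their summed geodesic area
#' reaches `coverage_target` of the total priority area, and emits one cell
#' rectangle polygon per selected cell, so realized coverage is within one
#' cell-area of the target.
#'
#' @param spec A [grid_spec()].
#' @param priority_mask An [nd_raster()]; cells with value > 0 are priority.
#' @param coverage_target Fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [polygon_set()]; attribute `"covered_cells"` holds chosen indices.
#' @export
make_protected_polygons <- function(spec, priority_mask, coverage_target, seed = 1) {
  if (coverage_target < 0 || coverage_target > 1)
    stop("coverage_target must be in [0, 1]", call. = FALSE)
  stopifnot(inherits(priority_mask, "nd_raster"))
  set.seed(seed)
  pm <- priority_mask$values
  pri <- which(!is.na(pm) & pm > 0)
  if (!length(pri)) stop("priority mask is empty", call. = FALSE)
  area <- cell_area_matrix(spec)
  total <- sum(area[pri])
  target_area <- coverage_target * total
  chosen <- integer(0)
  if (coverage_target > 0) {
    ord <- sample(pri)
    cum <- cumsum(area[ord])
    k <- sum(cum <= target_area + area[ord] / 2)
    chosen <- ord[seq_len(max(k, if (coverage_target > 0) 1 else 0))]
  }
  nr <- spec$nrows
  polys <- lapply(chosen, function(i) {
    r <- ((i - 1) %% nr) + 1; c <- ((i - 1) %/% nr) + 1
    w <- spec$xll + (c - 1) * spec$cellsize
    s <- spec$yll + (spec$nrows - r) * spec$cellsize
    e <- w + spec$cellsize; n <- s + spec$cellsize
    matrix(c(w, s, e, s, e, n, w, n, w, s), ncol = 2, byrow = TRUE)
  })
  ps <- polygon_set(polys)
  attr(ps, "covered_cells") <- chosen
  ps
}
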