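#' PCA of environmental values for niche-space analysis
#'
#' Variables are z-scored before the decomposition; the first two components
#' are retained. Sign convention: within each component the largest-magnitude
#' loading is made positive, so results are deterministic across platforms.
#'
#' @param env_values Data frame of environmental values at occurrence points
#'   (>= 3 rows, >= 2 variables).
#' @return Object of class `niche_pca`: `loadings` (variables x 2), `center`,
#'   `scale`, `explained` (variance fractions of PC1, PC2).
#' @export
fit_pca <- function(env_values) {
  env_values <- as.matrix(env_values)
  if (nrow(env_values) < 3 || ncol(env_values) < 2)
    stop("PCA needs >= 3 rows and >= 2 variables", call. = FALSE)
  sds <- apply(env_values, 2, stats::sd)
  if (any(sds == 0))
    stop("constant variable: PCA rank < 2", call. = FALSE)
  pc <- stats::prcomp(env_values, center = TRUE, scale. = TRUE)
  if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-12)
    stop("environmental values have rank < 2", call. = FALSE)
  load <- pc$rotation[, 1:2, drop = FALSE]
  for (k in 1:2) {
    i <- which.max(abs(load[, k]))
    if (load[i, k] < 0) load[, k] <- -load[, k]
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = load, center = pc$center, scale = pc$scale,
                 explained = expl[1:2]), class = "niche_pca")
}

#' Project environmental values onto the first two components
#'
#' @param pca A [fit_pca()] result.
#' @param env_values Data frame with the PCA's variables.
#' @return Two-column matrix of (PC1, PC2) scores.
#' @export
pca_scores <- function(pca, env_values) {
  x <- as.matrix(env_values[, names(pca$center), drop = FALSE])
  scale(x, center = pca$center, scale = pca$scale) %*% pca$loadings
}

#' Occurrence density grid in niche space
#'
#' Gaussian kernel density of a species' (PC1, PC2) scores evaluated at the
#' centers of a `grid_size x grid_size` lattice over a shared extent, then
#' renormalized to sum to 1 — the discrete density entering Schoener's D.
#' Per-axis bandwidths follow the normal-reference rule ([stats::bw.nrd()]) on
#' that species' scores, floored at 1% of the axis extent (with a warning)
#' when an axis is degenerate.
#'
#' @param scores Two-column matrix of niche-space coordinates (>= 5 rows).
#' @param extent List with `x = c(min, max)`, `y = c(min, max)`.
#' @param grid_size Cells per axis (default 35, i.e. 1225 grid points).
#' @return Object of class `niche_density_grid`: `grid` (matrix summing to 1),
#'   `extent`, `xc`/`yc` cell-center coordinates, `n` grid points, `bandwidth`.
#' @export
density_grid <- function(scores, extent, grid_size = 35) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 5)
    stop("kernel density needs >= 5 points", call. = FALSE)
  bw1 <- function(v, rng) {
    h <- tryCatch(stats::bw.nrd(v), error = function(e) 0)
    if (!is.finite(h) || h <= 0) {
      warning("degenerate axis: bandwidth floored at 1% of extent")
      h <- 0.01 * diff(rng)
    }
    h
  }
  hx <- bw1(scores[, 1], extent$x)
  hy <- bw1(scores[, 2], extent$y)
  xc <- seq(extent$x[1], extent$x[2], length.out = grid_size + 1)
  xc <- (xc[-1] + xc[-length(xc)]) / 2
  yc <- seq(extent$y[1], extent$y[2], length.out = grid_size + 1)
  yc <- (yc[-1] + yc[-length(yc)]) / 2
  dx <- outer(xc, scores[, 1], function(a, b) stats::dnorm((a - b) / hx))
  dy <- outer(yc, scores[, 2], function(a, b) stats::dnorm((a - b) / hy))
  g <- dx %*% t(dy) / (nrow(scores) * hx * hy)   # grid_size x grid_size, x rows
  if (sum(g) <= 0) stop("zero total density on the grid", call. = FALSE)
  g <- g / sum(g)
  structure(list(grid = g, extent = extent, xc = xc, yc = yc,
                 n = grid_size^2, bandwidth = c(hx, hy)),
            class = "niche_density_grid")
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum_i |p_i - q_i|` over matching density grids; 1 for
#' identical niches, 0 for disjoint ones.
#'
#' @param p,q `niche_density_grid`s with identical extents and shapes.
#' @return Scalar in `[0, 1]`.
#' @export
schoeners_d <- function(p, q) {
  stopifnot(inherits(p, "niche_density_grid"), inherits(q, "niche_density_grid"))
  if (!identical(dim(p$grid), dim(q$grid)) ||
      !isTRUE(all.equal(p$extent, q$extent)))
    stop("density grids have mismatched extent or shape", call. = FALSE)
  1 - 0.5 * sum(abs(p$grid - q$grid))
}

#' Pairwise Schoener's D matrix across species
#'
#' In the default `"pca"` mode, one PCA and one shared grid extent (pooled
#' score range plus a 10% margin per side) are used for every species, so all
#' densities live on the same 2-D lattice. The PCA is fitted on the pooled
#' occurrence points by default, or on a supplied `background` table
#' (background-calibrated niche space). In `"gradient"` mode, densities are
#' instead estimated per environmental variable on shared 1-D grids of
#' `grid_size` points; the pairwise D is the maximum of the per-variable D
#' values. Species with fewer than `min_points` records are excluded with a
#' warning.
#'
#' @param species_tables Named list: species -> data frame of environmental
#'   values at its occurrence points (same columns across species).
#' @param grid_size Density grid resolution per axis.
#' @param min_points Minimum records per species (default 5).
#' @param mode `"pca"` (2-D kernel densities in PC1-PC2 space) or
#'   `"gradient"` (per-variable 1-D densities, max-aggregated).
#' @param background Optional data frame of background environmental values;
#'   when given in `"pca"` mode the niche space is calibrated on it.
#' @return Object of class `overlap_matrix`: `D` (symmetric, unit diagonal),
#'   `n_zero_pairs`, `mode`, and in `"pca"` mode `pca`, `extent`, `grids`.
#' @export
overlap_matrix <- function(species_tables, grid_size = 35, min_points = 5,
                           mode = c("pca", "gradient"), background = NULL) {
  mode <- match.arg(mode)
  sizes <- vapply(species_tables, nrow, numeric(1))
  drop <- names(species_tables)[sizes < min_points]
  if (length(drop)) {
    warning(sprintf("excluding species with < %d points: %s", min_points,
                    paste(drop, collapse = ", ")))
    species_tables <- species_tables[sizes >= min_points]
  }
  if (length(species_tables) < 2)
    stop("need >= 2 species for an overlap matrix", call. = FALSE)
  if (mode == "gradient")
    return(overlap_matrix_gradient(species_tables, grid_size))
  pooled <- do.call(rbind, species_tables)
  pca <- fit_pca(if (is.null(background)) pooled else background)
  sc <- lapply(species_tables, function(tb) pca_scores(pca, tb))
  all_sc <- do.call(rbind, sc)
  margin <- function(rng) rng + c(-1, 1) * 0.1 * diff(rng)
  extent <- list(x = margin(range(all_sc[, 1])), y = margin(range(all_sc[, 2])))
  grids <- lapply(sc, density_grid, extent = extent, grid_size = grid_size)
  k <- length(grids)
  D <- matrix(1, k, k, dimnames = list(names(grids), names(grids)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    D[i, j] <- D[j, i] <- schoeners_d(grids[[i]], grids[[j]])
  structure(list(D = D,
                 n_zero_pairs = sum(D[upper.tri(D)] == 0),
                 mode = "pca", pca = pca, extent = extent, grids = grids),
            class = "overlap_matrix")
}

# Per-variable 1-D density overlap, aggregated by the maximum across
# variables (the "gradient" reading of the maximum value method).
overlap_matrix_gradient <- function(species_tables, grid_size) {
  vars <- colnames(species_tables[[1]])
  sp <- names(species_tables)
  k <- length(sp)
  D <- matrix(1, k, k, dimnames = list(sp, sp))
  per_var <- array(NA_real_, c(k, k, length(vars)),
                   dimnames = list(sp, sp, vars))
  for (v in vars) {
    pooled <- unlist(lapply(species_tables, function(tb) tb[[v]]))
    rng <- range(pooled) + c(-1, 1) * 0.1 * diff(range(pooled))
    centers <- seq(rng[1], rng[2], length.out = grid_size + 1)
    centers <- (centers[-1] + centers[-length(centers)]) / 2
    dens <- lapply(species_tables, function(tb) {
      x <- tb[[v]]
      h <- tryCatch(stats::bw.nrd(x), error = function(e) 0)
      if (!is.finite(h) || h <= 0) h <- 0.01 * diff(rng)
      d <- vapply(centers, function(cc) sum(stats::dnorm((cc - x) / h)),
                  numeric(1))
      d / sum(d)
    })
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      per_var[i, j, v] <- per_var[j, i, v] <-
        1 - 0.5 * sum(abs(dens[[i]] - dens[[j]]))
  }
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    D[i, j] <- D[j, i] <- max(per_var[i, j, ])
  structure(list(D = D, n_zero_pairs = sum(D[upper.tri(D)] == 0),
                 mode = "gradient", per_variable = per_var),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix> %d species, %d pair(s) with D = 0\n",
              nrow(x$D), x$n_zero_pairs))
  print(round(x$D, 3))
  invisible(x)
}

#' Cell-wise maximum composite of suitability rasters
#'
#' Integrates per-species predictions into a taxon-wide suitability surface by
#' taking the maximum suitability at each cell. Cells that are nodata in every
#' input stay nodata.
#'
#' @param species_rasters List of aligned [nd_raster()]s.
#' @return An `nd_raster`.
#' @export
composite_max <- function(species_rasters) {
  if (!length(species_rasters)) stop("no rasters supplied", call. = FALSE)
  spec <- species_rasters[[1]]$spec
  for (r in species_rasters)
    if (!specs_aligned(spec, r$spec))
      stop("composite inputs are not aligned", call. = FALSE)
  stacked <- vapply(species_rasters, function(r) as.vector(r$values),
                    numeric(spec$nrows * spec$ncols))
  stacked <- matrix(stacked, ncol = length(species_rasters))
  mx <- apply(stacked, 1, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  nd_raster(matrix(mx, spec$nrows, spec$ncols), spec)
}

#' Consistency between two suitability surfaces
#'
#' Pearson correlation over jointly valid cells plus the overlap ratio of
#' high-suitability areas: `100 * area(both >= cut) / area(either >= cut)`
#' (a Jaccard ratio on geodesic areas). The ratio is `NA` (flagged with a
#' warning) when neither raster reaches the cut anywhere.
#'
#' @param genus,composite Aligned [nd_raster()]s (e.g. a genus-level
#'   prediction and a species-composite).
#' @param high_cut High-suitability threshold (default 0.5).
#' @return List `pearson_r`, `overlap_ratio_pct`.
#' @export
consistency_metrics <- function(genus, composite, high_cut = 0.5) {
  if (!specs_aligned(genus$spec, composite$spec))
    stop("rasters are not aligned", call. = FALSE)
  a <- genus$values; b <- composite$values
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) stop("need >= 2 jointly valid cells", call. = FALSE)
  r <- stats::cor(a[ok], b[ok])
  area <- cell_area_matrix(genus$spec)
  both <- ok & a >= high_cut & b >= high_cut
  either <- ok & (a >= high_cut | b >= high_cut)
  ratio <- if (!any(either)) {
    warning("no cell reaches the high-suitability cut in either raster")
    NA_real_
  } else 100 * sum(area[both]) / sum(area[either])
  list(pearson_r = r, overlap_ratio_pct = ratio)
}
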