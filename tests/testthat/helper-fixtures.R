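# Shared fixtures, built in code at test time.

# Small grid for fast geometry tests.
tiny_spec <- function(ncols = 10, nrows = 8, xll = 100, yll = 20,
                      cellsize = 0.5, nodata = -9999) {
  grid_spec(ncols, nrows, xll, yll, cellsize, nodata)
}

# Raster of given values (recycled) on a tiny grid.
tiny_raster <- function(values, spec = tiny_spec()) {
  nd_raster(matrix(values, spec$nrows, spec$ncols), spec)
}

# 1-D Gibbs fixture: uniform background on [0,1], presences drawn with
# probability proportional to exp(lambda_true * x). Returns raw-value tables.
gibbs_fixture_1d <- function(lambda_true, m, B = 2000, seed = 1) {
  set.seed(seed)
  xb <- stats::runif(B)
  xp <- sample(xb, m, replace = TRUE, prob = exp(lambda_true * xb))
  list(presence = data.frame(x = xp), background = data.frame(x = xb))
}

# Independent grid-search oracle for the 1-D single-L-feature Gibbs MLE
# (no regularization): maximizes mean(lambda * x_p) - log(mean(exp(lambda * x_b))).
gibbs_mle_grid <- function(presence_x, background_x, grid = seq(-20, 20, by = 0.01)) {
  gain <- vapply(grid, function(l)
    mean(l * presence_x) - log(mean(exp(l * background_x))), numeric(1))
  grid[which.max(gain)]
}

# Brute-force count of distinct occupied cells (independent of cell_index):
# half-open convention via floor arithmetic on coordinates.
distinct_cells_oracle <- function(occ, spec, by_species = FALSE) {
  cx <- floor((occ$lon - spec$xll) / spec$cellsize)
  cy <- floor((occ$lat - spec$yll) / spec$cellsize)
  key <- paste(cx, cy)
  if (by_species) key <- paste(occ$species, key)
  length(unique(key))
}

# Row-subset a feature matrix, keeping its metadata attributes.
subset_features_test <- function(m, rows) {
  out <- m[rows, , drop = FALSE]
  attr(out, "feature_vars") <- attr(m, "feature_vars")
  attr(out, "feature_class") <- attr(m, "feature_class")
  out
}

# Random suitability raster in [0,1] with a few NA cells.
random_suitability <- function(spec, seed, na_frac = 0.05) {
  set.seed(seed)
  v <- matrix(stats::runif(spec$nrows * spec$ncols), spec$nrows, spec$ncols)
  v[sample(length(v), round(na_frac * length(v)))] <- NA
  nd_raster(v, spec)
}
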