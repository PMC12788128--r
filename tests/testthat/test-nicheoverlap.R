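test_that("niche PCA standardizes, orients deterministically and reports variance", {
  set.seed(2)
  x <- rnorm(200)
  # (near-)perfectly correlated pair: PC1 carries all the variance
  pca <- fit_pca(data.frame(a = x, b = 2 * x + 5 + rnorm(200, 0, 1e-8)))
  expect_gt(pca$explained[1], 0.999)
  expect_error(fit_pca(data.frame(a = x, b = rep(1, 200))), "rank|constant")

  iso <- as.data.frame(matrix(rnorm(2e4 * 2), ncol = 2))
  pi <- fit_pca(iso)
  expect_lt(abs(pi$explained[1] - 0.5), 0.03)
  expect_lt(abs(pi$explained[2] - 0.5), 0.03)
  # orthonormal loadings; projecting recovers standardized values (full rank)
  expect_equal(t(pi$loadings) %*% pi$loadings, diag(2), ignore_attr = TRUE)
  sc <- pca_scores(pi, iso)
  back <- sc %*% t(pi$loadings)
  expect_equal(back, scale(as.matrix(iso)), ignore_attr = TRUE)
  # sign convention: largest-magnitude loading positive
  expect_true(all(apply(pi$loadings, 2, function(l) l[which.max(abs(l))] > 0)))
})

test_that("density grids normalize to 1 and match brute-force KDE refinement", {
  set.seed(5)
  sc <- cbind(rnorm(80), rnorm(80, 2))
  ext <- list(x = c(-4, 4), y = c(-2, 6))
  g <- density_grid(sc, ext)
  expect_equal(sum(g$grid), 1)
  expect_equal(g$n, 1225)

  # mode location agrees with a 10x finer brute-force evaluation
  fine <- density_grid(sc, ext, grid_size = 350)
  cm <- which(g$grid == max(g$grid), arr.ind = TRUE)
  fm <- which(fine$grid == max(fine$grid), arr.ind = TRUE)
  expect_lt(abs(g$xc[cm[1]] - fine$xc[fm[1]]), diff(ext$x) / 35)
  expect_lt(abs(g$yc[cm[2]] - fine$yc[fm[2]]), diff(ext$y) / 35)

  # independent oracle: MASS::kde2d with matching bandwidths and grid
  k2 <- MASS::kde2d(sc[, 1], sc[, 2],
                    h = 4 * g$bandwidth,  # kde2d's h is 4x the Gaussian sd
                    n = 35, lims = c(range(g$xc), range(g$yc)))
  expect_equal(g$grid / sum(g$grid), k2$z / sum(k2$z), tolerance = 1e-6)

  # point mass with floored bandwidth concentrates in one cell (one
  # degenerate-axis warning per axis)
  expect_warning(expect_warning(
    pm <- density_grid(matrix(rep(c(0, 0), each = 6), 6, 2),
                       list(x = c(-1, 1), y = c(-1, 1))),
    "degenerate"), "degenerate")
  expect_gt(max(pm$grid), 0.9)
})

test_that("Schoener's D obeys its identities and the 1/1225 closed form", {
  set.seed(6)
  ext <- list(x = c(0, 1), y = c(0, 1))
  a <- density_grid(matrix(runif(60), 30, 2), ext)
  expect_equal(schoeners_d(a, a), 1)

  # uniform vs one-cell point mass: D = 1/G
  G <- 1225
  u <- a; u$grid <- matrix(1 / G, 35, 35)
  p <- a; p$grid <- matrix(0, 35, 35); p$grid[17, 17] <- 1
  expect_equal(schoeners_d(u, p), 1 / G)

  # disjoint supports
  q <- a; q$grid <- matrix(0, 35, 35); q$grid[1, 1] <- 1
  p2 <- a; p2$grid <- matrix(0, 35, 35); p2$grid[35, 35] <- 1
  expect_equal(schoeners_d(q, p2), 0)

  # random pairs: equality with an elementwise loop oracle, symmetry, range
  for (i in 1:5) {
    b <- density_grid(matrix(runif(60), 30, 2), ext)
    d <- schoeners_d(a, b)
    acc <- 0
    for (k in seq_along(a$grid)) acc <- acc + abs(a$grid[k] - b$grid[k])
    expect_equal(d, 1 - acc / 2)
    expect_equal(d, schoeners_d(b, a))
    expect_true(d >= 0 && d <= 1)
  }
  bad <- density_grid(matrix(runif(60), 30, 2), list(x = c(0, 2), y = c(0, 1)))
  expect_error(schoeners_d(a, bad), "mismatch")
})

test_that("overlap matrices share one PCA/grid and count zero pairs", {
  set.seed(7)
  tabs <- lapply(1:7, function(i)
    data.frame(a = rnorm(30, i * 3), b = rnorm(30)))
  names(tabs) <- paste0("sp", 1:7)
  ov <- overlap_matrix(tabs)
  expect_equal(dim(ov$D), c(7, 7))
  expect_equal(sum(upper.tri(ov$D)), 21)       # 21 unordered pairs
  expect_equal(diag(ov$D), rep(1, 7), ignore_attr = TRUE)
  expect_equal(ov$D, t(ov$D))
  exts <- lapply(ov$grids, function(g) g$extent)
  expect_true(all(vapply(exts, identical, logical(1), y = exts[[1]])))

  # duplicated species table: off-diagonal D = 1
  tabs2 <- list(s1 = tabs[[1]], s2 = tabs[[1]], s3 = tabs[[4]])
  ov2 <- overlap_matrix(tabs2)
  expect_equal(ov2$D["s1", "s2"], 1)

  expect_warning(ov3 <- overlap_matrix(c(tabs[1:2],
                                         list(tiny = tabs[[3]][1:3, ]))),
                 "excluding")
  expect_equal(nrow(ov3$D), 2)
})

test_that("gradient-mode overlap aggregates per-variable densities by maximum", {
  set.seed(19)
  tabs <- list(s1 = data.frame(a = rnorm(40), b = rnorm(40)),
               s2 = data.frame(a = rnorm(40, 6), b = rnorm(40)),
               s3 = data.frame(a = rnorm(40), b = rnorm(40)))
  ov <- overlap_matrix(tabs, mode = "gradient")
  expect_equal(ov$D, t(ov$D))
  expect_true(all(ov$D >= 0 & ov$D <= 1))
  # s1 and s2 share the b gradient, so max-aggregation keeps their D high
  expect_gt(ov$D["s1", "s2"], 0.7)
  expect_equal(ov$D["s1", "s2"], max(ov$per_variable["s1", "s2", ]))
  # a duplicated table gives D = 1 in every variable, hence overall
  ov2 <- overlap_matrix(list(x = tabs$s1, y = tabs$s1), mode = "gradient")
  expect_equal(ov2$D["x", "y"], 1)

  # background-calibrated PCA mode runs and stays within [0, 1]
  bg <- data.frame(a = rnorm(500, 2, 3), b = rnorm(500, 0, 2))
  ovb <- overlap_matrix(tabs, background = bg)
  expect_true(all(ovb$D >= 0 & ovb$D <= 1))
})

test_that("separation drives D between the generator's known extremes", {
  p0 <- make_species_pair(0, 500, seed = 3)
  t0 <- split(extract_at_points(p0$stack, p0$occ), p0$occ$species)
  expect_gte(overlap_matrix(t0)$D[1, 2], 0.85)
  p10 <- make_species_pair(10, 500, seed = 3)
  t10 <- split(extract_at_points(p10$stack, p10$occ), p10$occ$species)
  expect_lte(overlap_matrix(t10)$D[1, 2], 0.05)
})

test_that("composite maximum dominates its inputs cell-wise", {
  spec <- tiny_spec()
  a <- tiny_raster(0.2, spec); b <- tiny_raster(0.7, spec)
  expect_equal(composite_max(list(a))$values, a$values)
  expect_equal(composite_max(list(a, b))$values[1, 1], 0.7)
  rs <- lapply(1:4, function(i) random_suitability(spec, i))
  comp <- composite_max(rs)
  for (r in rs) {
    ok <- !is.na(r$values) & !is.na(comp$values)
    expect_true(all(comp$values[ok] >= r$values[ok]))
  }
  expect_error(composite_max(list(a, tiny_raster(1, tiny_spec(cellsize = 0.25)))),
               "aligned")
})

test_that("consistency metrics combine spatial correlation and high-area Jaccard", {
  spec <- tiny_spec()
  a <- random_suitability(spec, 1, na_frac = 0)
  m <- consistency_metrics(a, a)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$overlap_ratio_pct, 100)

  # disjoint high-suitability masks
  v1 <- matrix(0.1, spec$nrows, spec$ncols); v1[1:3, ] <- 0.9
  v2 <- matrix(0.1, spec$nrows, spec$ncols); v2[6:8, ] <- 0.9
  m2 <- consistency_metrics(nd_raster(v1, spec), nd_raster(v2, spec))
  expect_equal(m2$overlap_ratio_pct, 0)

  # textbook-formula oracle for r on flattened valid cells
  b <- random_suitability(spec, 2, na_frac = 0)
  m3 <- consistency_metrics(a, b)
  x <- as.vector(a$values); y <- as.vector(b$values)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(m3$pearson_r, r_oracle)

  # constant rasters: correlation is undefined (NA) and the high-area ratio
  # is flagged
  low <- nd_raster(matrix(0.1, spec$nrows, spec$ncols), spec)
  expect_warning(expect_warning(m4 <- consistency_metrics(low, low)), "no cell")
  expect_true(is.na(m4$overlap_ratio_pct))
})
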