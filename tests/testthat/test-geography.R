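test_that("high-suitability centroids are area-weighted cell-center means", {
  spec <- grid_spec(10, 10, 100, 20, 0.5)
  v <- matrix(0.2, 10, 10); v[3, 4] <- 0.9
  cls <- classify_suitability(nd_raster(v, spec))
  cent <- centroid_high(cls)
  expect_equal(unname(cent), unlist(cell_center(spec, 3, 4)), ignore_attr = TRUE)

  # mask symmetric about the equator and a central meridian
  spec_eq <- grid_spec(10, 10, -2.5, -2.5, 0.5)
  v2 <- matrix(0.0, 10, 10); v2[4:7, 4:7] <- 0.8   # symmetric block
  cent2 <- centroid_high(classify_suitability(nd_raster(v2, spec_eq)))
  expect_equal(unname(cent2["lon"]), 0)
  expect_equal(unname(cent2["lat"]), 0, tolerance = 1e-12)

  # brute-force oracle on a random mask + longitude-translation equivariance
  p <- random_suitability(spec, 8)
  cls3 <- classify_suitability(p)
  cent3 <- centroid_high(cls3)
  area <- cell_area_matrix(spec)
  num_lon <- num_lat <- den <- 0
  for (r in 1:10) for (cc in 1:10) {
    if (!is.na(cls3$values[r, cc]) && cls3$values[r, cc] == 3) {
      ctr <- cell_center(spec, r, cc)
      num_lon <- num_lon + area[r, cc] * ctr$lon
      num_lat <- num_lat + area[r, cc] * ctr$lat
      den <- den + area[r, cc]
    }
  }
  expect_equal(unname(cent3), c(num_lon / den, num_lat / den))
  spec_sh <- grid_spec(10, 10, 110, 20, 0.5)
  cent_sh <- centroid_high(classify_suitability(nd_raster(p$values, spec_sh)))
  expect_equal(unname(cent_sh["lon"] - cent3["lon"]), 10)
  expect_equal(cent_sh["lat"], cent3["lat"])

  expect_error(centroid_high(classify_suitability(
    nd_raster(matrix(0.2, 10, 10), spec))), "no highly suitable")
})

test_that("haversine distances match closed forms and an independent implementation", {
  expect_equal(haversine_km(c(100, 30), c(100, 30)), 0)
  # 1 degree of longitude along the equator = 2*pi*R/360
  expect_equal(haversine_km(c(0, 0), c(1, 0)), 2 * pi * 6371.0088 / 360,
               tolerance = 1e-9)
  set.seed(14)
  for (i in 1:10) {
    a <- c(runif(1, -179, 179), runif(1, -89, 89))
    b <- c(runif(1, -179, 179), runif(1, -89, 89))
    cc <- c(runif(1, -179, 179), runif(1, -89, 89))
    expect_lte(haversine_km(a, b),
               haversine_km(a, cc) + haversine_km(cc, b) + 1e-9)
    expect_equal(haversine_km(a, b), haversine_km(b, a))
    expect_equal(haversine_km(a, b),
                 geosphere::distHaversine(a, b, r = 6371008.8) / 1000,
                 tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis reproduces the published centroid test and the stats oracle", {
  # three groups of n = 3 with rank sums 20, 7, 18 (mean ranks 6.67, 2.33, 6.00):
  # tie-free data whose pooled ranks are {5,7,8}, {1,2,4}, {3,6,9}
  groups <- list(c(25, 33, 38), c(5, 9, 17), c(13, 29, 41))
  kw <- kruskal_wallis(groups)
  expect_equal(round(kw$mean_ranks, 2), c(6.67, 2.33, 6.00))
  expect_equal(round_half_away(kw$H), 4.36)
  expect_equal(kw$df, 2)
  expect_equal(round(kw$p_value, 2), 0.11)

  # identical groups: H = 0, p = 1
  same <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)

  # oracle: stats::kruskal.test on random data with ties
  set.seed(15)
  for (i in 1:5) {
    g <- list(sample(1:6, 7, TRUE), sample(1:6, 5, TRUE), sample(1:6, 6, TRUE))
    ours <- kruskal_wallis(g)
    ref <- stats::kruskal.test(g)
    expect_equal(ours$H, unname(ref$statistic))
    expect_equal(ours$p_value, unname(ref$p.value))
  }

  # invariance under strictly monotone transforms (tie-free data)
  g <- list(rnorm(4), rnorm(5), rnorm(4))
  expect_equal(kruskal_wallis(g)$H, kruskal_wallis(lapply(g, exp))$H)

  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("KW p-values agree with a permutation null within Monte-Carlo error", {
  set.seed(16)
  g <- list(rnorm(4), rnorm(4, 0.5), rnorm(4, 1))
  kw <- kruskal_wallis(g)
  x <- unlist(g)
  sizes <- lengths(g)
  n_perm <- 20000
  stat <- function(xs) {
    parts <- split(xs, rep(seq_along(sizes), sizes))
    kruskal_wallis(parts)$H
  }
  perm <- replicate(n_perm, stat(sample(x)))
  p_mc <- mean(perm >= kw$H - 1e-12)
  mc_err <- 3 * sqrt(p_mc * (1 - p_mc) / n_perm)
  # chi-square is an approximation at n = 4 per group: allow approximation slack
  expect_lt(abs(kw$p_value - p_mc), mc_err + 0.05)
})

test_that("gap analysis covers priority cells by center-in-polygon and reports areas", {
  expect_equal(gap_result(145.62, 6.46)$coverage_pct, 100 * 6.46 / 145.62)
  expect_equal(round_half_away(gap_result(145.62, 6.46)$coverage_pct), 4.44)
  g <- gap_result(10, 2.5)
  expect_equal(g$coverage_pct + g$gap_pct, 100)

  spec <- grid_spec(20, 16, 100, 25, 0.1)
  v <- matrix(0.05, 16, 20); v[5:10, 5:14] <- 0.6
  cls <- classify_suitability(nd_raster(v, spec))
  everything <- polygon_set(list(matrix(c(99, 24, 103, 24, 103, 28, 99, 28),
                                        ncol = 2, byrow = TRUE)))
  full <- gap_analysis(cls, everything)
  expect_equal(full$coverage_pct, 100)
  expect_equal(full$gap_pct, 0)

  pri <- nd_raster((cls$values >= 2) * 1, spec)
  ps <- make_protected_polygons(spec, pri, 0.3, seed = 5)
  got <- gap_analysis(cls, ps)
  one_cell_pct <- 100 * max(cell_area_km2(spec)) /
    sum(cell_area_matrix(spec)[cls$values >= 2])
  expect_lt(abs(got$coverage_pct - 30), one_cell_pct + 1e-9)

  expect_error(gap_analysis(classify_suitability(
    nd_raster(matrix(0.05, 16, 20), spec)), everything), "empty")
})

test_that("scenario gap series equals per-period gap analyses", {
  spec <- grid_spec(20, 16, 100, 25, 0.1)
  set.seed(17)
  base <- nd_raster(matrix(runif(320, 0.2, 0.9), 16, 20), spec)
  scen <- make_scenario_set(base, list(S = list(
    list(period = "p1", expand = 0, contract = 0),
    list(period = "p2", expand = 0, contract = 0))), seed = 1)
  pri <- nd_raster((classify_suitability(base)$values >= 2) * 1, spec)
  ps <- make_protected_polygons(spec, pri, 0.5, seed = 2)
  series <- scenario_gap_series(scen, ps)
  expect_equal(nrow(series), 3)
  # constant rasters across periods -> constant series
  expect_equal(length(unique(series$coverage_pct)), 1)
  direct <- gap_analysis(classify_suitability(scen$rasters$S$p1), ps)
  expect_equal(series$coverage_pct[series$period == "p1"], direct$coverage_pct)
})

test_that("centroid tracks hold one centroid per period and n-1 distances", {
  spec <- grid_spec(12, 12, 100, 20, 0.25)
  mk <- function(rs, cs) {
    v <- matrix(0.2, 12, 12); v[rs, cs] <- 0.9
    classify_suitability(nd_raster(v, spec))
  }
  cls <- list(current = mk(3:4, 3:4), p1 = mk(4:5, 4:5), p2 = mk(6:7, 6:7))
  tr <- centroid_track(cls, scenario = "S")
  expect_equal(nrow(tr$track), 3)
  expect_length(tr$distances_km, 2)
  expect_true(all(tr$distances_km > 0))
  expect_equal(tr$distances_km[1],
               haversine_km(c(tr$track$lon[1], tr$track$lat[1]),
                            c(tr$track$lon[2], tr$track$lat[2])))
})
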