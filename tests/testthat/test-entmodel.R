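test_that("feature expansion has the documented columns and scaling", {
  bg <- data.frame(x = c(0, 5, 10), y = c(2, 4, 6))
  fs <- feature_spec("L", "x", bg)
  f <- build_features(fs, data.frame(x = c(0, 2.5, 10)))
  expect_equal(ncol(f), 1)
  expect_equal(as.vector(f), c(0, 0.25, 1))  # min -> 0, max -> 1

  expect_equal(ncol(build_features(feature_spec("LQ", c("x", "y"), bg),
                                   bg)), 4)
  # LQPH with 2 variables, 5 knots: 2L + 2Q + 1P + 2*2*5 H = 25
  f25 <- build_features(feature_spec("LQPH", c("x", "y"), bg, hinge_knots = 5), bg)
  expect_equal(ncol(f25), 25)
  cls <- attr(f25, "feature_class")
  expect_equal(unname(table(cls)[c("L", "Q", "P", "H")]), c(2L, 2L, 1L, 20L),
               ignore_attr = TRUE)
  # all features within [0, 1]
  expect_true(all(f25 >= 0 & f25 <= 1))

  bgc <- data.frame(x = c(1, 1, 1), y = c(0, 1, 2))
  expect_warning(fc <- build_features(feature_spec("LQ", c("x", "y"), bgc), bgc),
                 "constant")
  expect_equal(colnames(fc), c("L_x", "L_y", "Q_y"))
})

test_that("overwhelming regularization yields the null model; its logistic output is 0.5", {
  fx <- gibbs_fixture_1d(3, m = 100, seed = 2)
  fit <- fit_maxent_on("LQ", fx$presence, fx$background, rm = 1e6)
  expect_true(all(fit$lambdas == 0))
  expect_equal(fit$training_gain, 0)
  fb <- build_features(attr(fit, "feature_spec"), fx$background)
  expect_equal(unique(logistic_scores(fit, fb)), 0.5)
  expect_equal(sum(exp(fb %*% fit$lambdas) / fit$Z), 1)  # raw normalization
  expect_equal(fit$entropy_H, log(nrow(fx$background)))
})

test_that("uninformative presences produce near-zero training gain", {
  set.seed(6)
  xb <- runif(2000)
  pres <- data.frame(x = sample(xb, 500, replace = TRUE))
  fit <- fit_maxent_on("LQ", pres, data.frame(x = xb), rm = 1)
  expect_lte(fit$training_gain, 0.05)
})

test_that("a one-variable Gibbs truth is recovered within 10% of the grid-search oracle", {
  fx <- gibbs_fixture_1d(3, m = 2000, B = 2000, seed = 1)
  fit <- fit_maxent_on("L", fx$presence, fx$background, rm = 0.01)
  oracle <- gibbs_mle_grid(fx$presence$x, fx$background$x)
  expect_lt(abs(fit$lambdas[["L_x"]] - oracle) / abs(oracle), 0.10)
  expect_lt(abs(fit$lambdas[["L_x"]] - 3) / 3, 0.10)
})

test_that("training gain is monotone per sweep and coefficients shrink with RM", {
  fx <- gibbs_fixture_1d(4, m = 200, B = 500, seed = 3)
  fit <- fit_maxent_on("LQ", fx$presence, fx$background, rm = 1)
  expect_true(all(diff(fit$gain_trace) >= -1e-9))
  l1 <- vapply(c(1, 10, 100, 1e4), function(rm)
    sum(abs(fit_maxent_on("LQ", fx$presence, fx$background, rm = rm)$lambdas)),
    numeric(1))
  expect_true(all(diff(l1) <= 1e-9))
  expect_equal(l1[4], 0)
})

test_that("raw and logistic outputs rank cells identically", {
  fx <- gibbs_fixture_1d(2, m = 100, B = 300, seed = 5)
  fit <- fit_maxent_on("LQ", fx$presence, fx$background, rm = 0.5)
  fb <- build_features(attr(fit, "feature_spec"), fx$background)
  expect_equal(order(raw_scores <- exp(fb %*% fit$lambdas)),
               order(logistic_scores(fit, fb)))
})

test_that("AUC follows the rank formula, the trapezoid oracle and the banding", {
  expect_equal(as.numeric(auc(c(3, 4, 5), c(0, 1, 2))), 1)
  expect_equal(as.numeric(auc(c(1, 2), c(1, 2))), 0.5)
  expect_equal(auc_band(0.918), "high performance")
  expect_equal(auc_band(0.85), "moderate performance")
  expect_equal(auc_band(0.6), "poor performance")
  expect_warning(a <- auc(c(1, 1), c(1, 1, 1)), "constant")
  expect_equal(as.numeric(a), 0.5)

  # trapezoidal ROC integration oracle on random scores
  set.seed(9)
  for (i in 1:5) {
    sp <- rnorm(40, 1); sb <- rnorm(60)
    cuts <- sort(unique(c(-Inf, sp, sb, Inf)), decreasing = TRUE)
    tpr <- vapply(cuts, function(t) mean(sp >= t), numeric(1))
    fpr <- vapply(cuts, function(t) mean(sb >= t), numeric(1))
    trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    expect_equal(as.numeric(auc(sp, sb)), trap, tolerance = 1e-12)
  }
})

test_that("AICc matches closed forms and flags overparameterized candidates", {
  fx <- gibbs_fixture_1d(2, m = 30, B = 400, seed = 7)
  null <- fit_maxent_on("L", fx$presence, fx$background, rm = 1e6)
  fs <- attr(null, "feature_spec")
  fp <- build_features(fs, fx$presence); fb <- build_features(fs, fx$background)
  ic0 <- aicc(null, fp, fb)
  n <- nrow(fp); N <- nrow(fb)
  expect_equal(ic0$k, 0)
  expect_equal(ic0$lnL, -n * log(N))           # uniform model closed form
  expect_equal(ic0$aicc, 2 * n * log(N))

  fit <- fit_maxent_on("L", fx$presence, fx$background, rm = 0.5)
  ic <- aicc(fit, fp, fb)
  # hand-computed from (k, lnL, n) by the formula
  expect_equal(ic$aicc,
               2 * ic$k - 2 * ic$lnL + 2 * ic$k * (ic$k + 1) / (n - ic$k - 1))

  tiny <- subset_features_test(fp, 1:2)
  expect_false(aicc(fit, tiny, fb)$valid)      # k >= n - 1
})

test_that("the default tuning grid enumerates 48 candidates and selects delta AICc 0", {
  fx <- gibbs_fixture_1d(3, m = 40, B = 250, seed = 4)
  tn <- tune_maxent(fx$presence, fx$background, hinge_knots = 3,
                    test_fraction = 0.25, seed = 1)
  expect_equal(nrow(tn$results), 48)           # 8 RM x 6 FC
  best <- tn$results[tn$best, ]
  expect_equal(best$delta_aicc, 0)
  expect_true(all(tn$results$delta_aicc >= 0, na.rm = TRUE))
  # tie rule: among delta = 0 candidates the higher test AUC wins
  cand <- tn$results[tn$results$valid & tn$results$delta_aicc == 0, ]
  expect_equal(best$auc_test, max(cand$auc_test))
})

test_that("jackknife gains isolate informative variables", {
  set.seed(10)
  B <- 600
  bg <- data.frame(x = runif(B), z = runif(B))      # z is pure noise
  pres_idx <- sample(B, 300, replace = TRUE, prob = exp(4 * bg$x))
  pres <- bg[pres_idx, ]
  jk <- jackknife_gains("LQ", pres, bg, rm = 1)
  full <- jk$gain_full[1]
  expect_true(all(jk$gain_without <= full + 1e-6))
  expect_lt(jk$gain_only[jk$variable == "z"], 0.05)         # noise: ~0 gain
  expect_gt(jk$gain_only[jk$variable == "x"], 0.9 * full)   # informative: ~full
})

test_that("response curves recover a quadratic optimum and stay in (0,1)", {
  set.seed(11)
  B <- 1500
  bg <- data.frame(x = runif(B))
  x_star <- 0.6
  pres <- bg[sample(B, 800, replace = TRUE,
                    prob = exp(-30 * (bg$x - x_star)^2)), , drop = FALSE]
  fit <- fit_maxent_on("LQ", pres, bg, rm = 0.1)
  rc <- response_curve(fit, "x", pres, bg, mode = "only")
  expect_true(all(rc$suitability > 0 & rc$suitability < 1))
  expect_lt(abs(rc$value[which.max(rc$suitability)] - x_star), 0.05)
  # only-mode on a single-variable model is the same as predicting the gradient
  rc_m <- response_curve(fit, "x", pres, bg, mode = "marginal")
  expect_equal(rc$suitability, rc_m$suitability, tolerance = 1e-6)
})

test_that("percent contributions are normalized credits per variable", {
  fx <- gibbs_fixture_1d(3, m = 200, B = 500, seed = 8)
  fit <- fit_maxent_on("L", fx$presence, fx$background, rm = 0.5)
  pc <- percent_contribution(fit)
  expect_equal(unname(pc["x"]), 100)
  # duplicated variable splits but the total matches the single-variable credit
  pres2 <- data.frame(x = fx$presence$x, x2 = fx$presence$x)
  bg2 <- data.frame(x = fx$background$x, x2 = fx$background$x)
  fit2 <- fit_maxent_on("L", pres2, bg2, rm = 0.5)
  pc2 <- percent_contribution(fit2)
  expect_equal(sum(pc2), 100, tolerance = 1e-6)
})

test_that("replicate schemes follow the published size strata", {
  g <- replicate_scheme(534, "genus")
  expect_equal(g, list(method = "subsample", test_fraction = 0.25, n_replicates = 10))
  expect_equal(replicate_scheme(259, "species")$test_fraction, 0.30)
  expect_equal(replicate_scheme(32, "species")$test_fraction, 0.40)
  b <- replicate_scheme(8, "species")
  expect_equal(b$method, "bootstrap")
  expect_equal(b$test_fraction, 0)
  expect_warning(gap <- replicate_scheme(17, "species"), "rule gap")
  expect_equal(gap$test_fraction, 0.40)
})

test_that("prediction over a stack names missing variables and respects nodata", {
  st <- make_env_stack(21, n_vars = 2,
                       spec = grid_spec(30, 25, 100, 25, 0.05))
  tm <- truth_model(list(Bio1 = c(2, -1)))
  occ <- sample_occurrences(tm, st, 150, seed = 3)
  pres <- extract_at_points(st, occ)
  bg <- background_table(st, seed = 1)
  fit <- fit_maxent_on("LQ", pres, bg, rm = 1)
  suit <- predict(fit, st)
  expect_true(all(suit$values > 0 & suit$values < 1, na.rm = TRUE))
  st1 <- env_stack(st$layers["Bio2"])
  expect_error(predict(fit, st1), "Bio1")
})
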