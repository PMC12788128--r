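#' Fit a maximum-entropy model from variable tables
#'
#' Convenience wrapper: constructs the feature specification from the
#' background table, expands both tables and calls [fit_maxent()]. The
#' returned model carries the feature spec so [predict.maxent_model()] works
#' directly on stacks.
#'
#' @param classes Feature-class string or vector (see [feature_spec()]).
#' @param presence_table,background_table Data frames of raw variable values.
#' @param variables Variables to use (default: all background columns).
#' @param rm Regularization multiplier.
#' @param hinge_knots Knots per variable per hinge direction.
#' @param ... Passed to [fit_maxent()].
#' @return A `maxent_model` with attribute `"feature_spec"`.
#' @export
fit_maxent_on <- function(classes, presence_table, background_table,
                          variables = colnames(background_table), rm = 1,
                          hinge_knots = 20, ...) {
  fs <- feature_spec(classes, variables, background_table, hinge_knots)
  fp <- build_features(fs, presence_table)
  fb <- build_features(fs, background_table)
  model <- fit_maxent(fp, fb, rm = rm, ...)
  attr(model, "feature_spec") <- fs
  model
}

#' Select background cells from a stack
#'
#' All valid cells when there are at most `max_background`; otherwise a seeded
#' sample of `max_background` cells without replacement.
#'
#' @param stack An [env_stack()].
#' @param max_background Cap on background size (default 10000).
#' @param seed Integer seed for the subsample.
#' @return Data frame of background variable values.
#' @export
background_table <- function(stack, max_background = 10000, seed = 1) {
  vals <- sapply(names(stack$layers), function(v)
    as.vector(stack$layers[[v]]$values))
  vals <- as.data.frame(matrix(vals, ncol = length(stack$layers),
                               dimnames = list(NULL, names(stack$layers))))
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  if (nrow(vals) > max_background) {
    set.seed(seed)
    vals <- vals[sample(nrow(vals), max_background), , drop = FALSE]
  }
  rownames(vals) <- NULL
  vals
}

#' Replicate scheme by sample size
#'
#' Genus-level models use subsampling with 25% test data; species-level models
#' use a size-stratified rule — `n >= 50`: 30% test; `20 <= n < 50`: 40% test;
#' `n < 15`: bootstrap with no held-out test. The `15 <= n < 20` range is not
#' covered by the published rule and is mapped to 40% test with a warning.
#' Ten replicates throughout; replicate suitability rasters are averaged
#' cell-wise.
#'
#' @param n Number of occurrence records (>= 1).
#' @param level `"genus"` or `"species"`.
#' @return List `method` (`"subsample"` or `"bootstrap"`), `test_fraction`,
#'   `n_replicates`.
#' @export
replicate_scheme <- function(n, level = c("genus", "species")) {
  level <- match.arg(level)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (level == "genus")
    return(list(method = "subsample", test_fraction = 0.25, n_replicates = 10))
  if (n >= 50) list(method = "subsample", test_fraction = 0.30, n_replicates = 10)
  else if (n >= 20) list(method = "subsample", test_fraction = 0.40, n_replicates = 10)
  else if (n >= 15) {
    warning("sample size in [15, 20): rule gap, using subsample with 40% test")
    list(method = "subsample", test_fraction = 0.40, n_replicates = 10)
  } else list(method = "bootstrap", test_fraction = 0, n_replicates = 10)
}

#' Tune the regularization multiplier and feature combination by AICc
#'
#' Evaluates every candidate on the RM x FC grid (default 8 x 6 = 48
#' candidates): each is fitted on all presences, scored by AICc over the
#' background cells, and given train/test AUCs from a single seeded
#' subsample split. The candidate with `delta_AICc = 0` is selected; ties are
#' broken by higher test AUC, then fewer parameters, then lexicographic FC.
#'
#' @param presence_table,background_table Data frames of raw variable values.
#' @param rm_grid Regularization multipliers (default `seq(0.5, 4, by = 0.5)`).
#' @param fc_menu Feature combinations (default
#'   `c("L","H","LQ","LQH","LQPH","LQPHT")`).
#' @param hinge_knots Knots for H/T features.
#' @param test_fraction Held-out presence fraction for the test AUC.
#' @param seed Seed for the split.
#' @param ... Passed to [fit_maxent()].
#' @return Object of class `tune_result`: `results` (one row per candidate:
#'   fc, rm, k, lnL, aicc, delta_aicc, auc_train, auc_test, valid), `best`
#'   (row index), and `model` (refit of the winner on all presences).
#' @export
tune_maxent <- function(presence_table, background_table,
                        rm_grid = seq(0.5, 4, by = 0.5),
                        fc_menu = c("L", "H", "LQ", "LQH", "LQPH", "LQPHT"),
                        hinge_knots = 20, test_fraction = 0.25, seed = 1, ...) {
  if (!length(rm_grid) || !length(fc_menu))
    stop("rm_grid and fc_menu must be non-empty", call. = FALSE)
  n <- nrow(presence_table)
  set.seed(seed)
  test_idx <- if (test_fraction > 0 && n >= 4)
    sample(n, max(1, round(test_fraction * n))) else integer(0)
  train_idx <- setdiff(seq_len(n), test_idx)
  res <- NULL
  for (fc in fc_menu) for (rm in rm_grid) {
    fs <- feature_spec(fc, colnames(background_table), background_table,
                       hinge_knots)
    fp <- build_features(fs, presence_table)
    fb <- build_features(fs, background_table)
    fit_all <- fit_maxent(fp, fb, rm = rm, ...)
    ic <- aicc(fit_all, fp, fb)
    fit_tr <- if (length(test_idx))
      fit_maxent(subset_features(fp, train_idx), fb, rm = rm, ...) else fit_all
    auc_tr <- as.numeric(auc(logistic_scores(fit_tr, fp[train_idx, , drop = FALSE]),
                             logistic_scores(fit_tr, fb)))
    auc_te <- if (length(test_idx))
      as.numeric(auc(logistic_scores(fit_tr, fp[test_idx, , drop = FALSE]),
                     logistic_scores(fit_tr, fb))) else NA_real_
    res <- rbind(res, data.frame(fc = fc, rm = rm, k = ic$k, lnL = ic$lnL,
                                 aicc = ic$aicc, auc_train = auc_tr,
                                 auc_test = auc_te, valid = ic$valid,
                                 stringsAsFactors = FALSE))
  }
  if (!any(res$valid)) stop("all tuning candidates are invalid", call. = FALSE)
  res$delta_aicc <- res$aicc - min(res$aicc[res$valid], na.rm = TRUE)
  cand <- which(res$valid & res$delta_aicc == 0)
  te <- ifelse(is.na(res$auc_test[cand]), res$auc_train[cand], res$auc_test[cand])
  ord <- order(-te, res$k[cand], res$fc[cand])
  best <- cand[ord[1]]
  model <- fit_maxent_on(res$fc[best], presence_table, background_table,
                         rm = res$rm[best], hinge_knots = hinge_knots, ...)
  structure(list(results = res, best = best, model = model),
            class = "tune_result")
}

#' @export
print.tune_result <- function(x, ...) {
  b <- x$results[x$best, ]
  cat(sprintf("<tune_result> %d candidates; selected FC = %s, RM = %g (AICc %.2f, test AUC %s)\n",
              nrow(x$results), b$fc, b$rm, b$aicc,
              ifelse(is.na(b$auc_test), "NA", sprintf("%.3f", b$auc_test))))
  invisible(x)
}

#' Jackknife variable importance
#'
#' For each variable, refits the model with only that variable and without it
#' (same feature classes and RM) and reports the training gains alongside the
#' full-model gain.
#'
#' @param classes Feature-class string.
#' @param presence_table,background_table Data frames of raw variable values.
#' @param rm Regularization multiplier.
#' @param hinge_knots Hinge/threshold knots.
#' @param ... Passed to [fit_maxent()].
#' @return Data frame: `variable`, `gain_only`, `gain_without`, `gain_full`.
#' @export
jackknife_gains <- function(classes, presence_table, background_table, rm = 1,
                            hinge_knots = 20, ...) {
  vars <- colnames(background_table)
  if (length(vars) < 2) stop("jackknife needs >= 2 variables", call. = FALSE)
  gain_for <- function(v) fit_maxent_on(classes, presence_table,
                                        background_table, variables = v,
                                        rm = rm, hinge_knots = hinge_knots,
                                        ...)$training_gain
  full <- gain_for(vars)
  data.frame(variable = vars,
             gain_only = vapply(vars, function(v) gain_for(v), numeric(1)),
             gain_without = vapply(vars, function(v) gain_for(setdiff(vars, v)),
                                   numeric(1)),
             gain_full = full, row.names = NULL)
}

#' Response curves of a fitted model
#'
#' `marginal`: the variable sweeps its background range while the others are
#' held at their presence means. `only`: a fresh single-variable model (same
#' classes and RM) is fitted and swept. 100 evenly spaced samples; logistic
#' output.
#'
#' @param model A `maxent_model` with a feature spec (from [fit_maxent_on()]).
#' @param variable Variable name.
#' @param presence_table,background_table Tables the model was fitted on
#'   (required; used for presence means and for `only`-mode refits).
#' @param mode `"marginal"` or `"only"`.
#' @param n_points Curve resolution.
#' @return Data frame with columns `value` and `suitability`.
#' @export
response_curve <- function(model, variable, presence_table, background_table,
                           mode = c("marginal", "only"), n_points = 100) {
  mode <- match.arg(mode)
  fs <- attr(model, "feature_spec")
  if (is.null(fs) || !(variable %in% fs$variables))
    stop(sprintf("variable '%s' is not in the model", variable), call. = FALSE)
  rng <- fs$range[[variable]]
  xs <- seq(rng[1], rng[2], length.out = n_points)
  if (mode == "only") {
    m1 <- fit_maxent_on(paste(fs$classes, collapse = ""), presence_table,
                        background_table, variables = variable, rm = model$rm,
                        hinge_knots = fs$hinge_knots)
    grid <- data.frame(xs); names(grid) <- variable
    f <- build_features(attr(m1, "feature_spec"), grid)
    return(data.frame(value = xs, suitability = logistic_scores(m1, f)))
  }
  grid <- as.data.frame(lapply(fs$variables, function(v)
    rep(mean(presence_table[[v]]), n_points)))
  names(grid) <- fs$variables
  grid[[variable]] <- xs
  f <- build_features(fs, grid)
  data.frame(value = xs, suitability = logistic_scores(model, f))
}

#' Percent contribution of each variable
#'
#' During coordinate descent every accepted update's gain increment is
#' credited to the feature's underlying variable (product features split
#' 50/50 between their two variables); credits are clipped at zero and
#' normalized to sum to 100.
#'
#' @param model A `maxent_model`.
#' @return Named numeric vector of percent contributions (sums to 100, or all
#'   zero with a warning if no credit accrued).
#' @export
percent_contribution <- function(model) {
  vars <- unique(unlist(model$feature_vars))
  acc <- stats::setNames(rep(0, length(vars)), vars)
  for (j in seq_along(model$credit)) {
    cr <- max(model$credit[j], 0)
    fv <- model$feature_vars[[j]]
    acc[fv] <- acc[fv] + cr / length(fv)
  }
  tot <- sum(acc)
  if (tot <= 0) {
    warning("no gain credit accrued: contributions are all zero")
    return(acc)
  }
  100 * acc / tot
}
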