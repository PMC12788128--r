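#' Per-class base regularization penalties
#'
#' Base penalty `base(class, m)` interpolated in the presence sample size `m`
#' (clamped at the tabulated ends): linear/quadratic/product on
#' `{(10, 1.0), (30, 0.2), (100, 0.05)}`, hinge constant 0.5, threshold on
#' `{(10, 2), (100, 1)}`.
#'
#' @param class Feature class letter (`"L"`, `"Q"`, `"P"`, `"H"`, `"T"`).
#' @param m Number of presence records.
#' @return Scalar base penalty.
#' @export
base_penalty <- function(class, m) {
  switch(class,
         L = , Q = , P = stats::approx(c(10, 30, 100), c(1, 0.2, 0.05),
                                       xout = m, rule = 2)$y,
         H = 0.5,
         T = stats::approx(c(10, 100), c(2, 1), xout = m, rule = 2)$y,
         stop("unknown feature class", call. = FALSE))
}

#' Fit an L1-regularized maximum-entropy (Gibbs) model
#'
#' Maximizes the regularized training gain
#' \deqn{G(\lambda) = \bar f_p \cdot \lambda - \log \left( \tfrac1B \sum_b e^{\lambda \cdot f_b} \right) - \sum_j \beta_j |\lambda_j|}
#' where \eqn{\bar f_p} are presence feature means and the log-partition runs
#' over background rows; the null model (\eqn{\lambda = 0}) has gain 0.
#' Per-feature penalties are
#' \eqn{\beta_j = \mathrm{rm} \times \mathrm{base}(\mathrm{class}, m) \times s_j / \sqrt m}
#' with \eqn{s_j} the presence standard deviation of feature j (floored at
#' 1e-4). Optimization is cyclic coordinate-wise proximal (Newton +
#' soft-threshold) descent with per-coordinate backtracking, so the gain never
#' decreases; convergence is declared when a full sweep improves the gain by
#' less than `tol`.
#'
#' @param presence Feature matrix of presence rows (from [build_features()]).
#' @param background Feature matrix of background rows, same columns.
#' @param rm Regularization multiplier (> 0); larger values give sparser,
#'   smoother models.
#' @param tol Convergence tolerance on the per-sweep gain improvement.
#' @param max_sweeps Sweep cap; non-convergence yields a warning, not an error.
#' @return Object of class `maxent_model`: `lambdas`, `feature_class`,
#'   `feature_vars`, `Z` (background partition sum), `entropy_H` (entropy of
#'   the raw background distribution), `rm`, `training_gain`, `gain_trace`
#'   (per-sweep gains), `credit` (per-variable gain credit for
#'   [percent_contribution()]), `bg_means` and column names.
#' @export
fit_maxent <- function(presence, background, rm = 1, tol = 1e-6,
                       max_sweeps = 500) {
  if (rm <= 0) stop("rm must be > 0", call. = FALSE)
  if (nrow(presence) < 1) stop("need at least one presence row", call. = FALSE)
  if (nrow(background) < 100)
    stop("need at least 100 background rows", call. = FALSE)
  if (!all(is.finite(presence)) || !all(is.finite(background)))
    stop("non-finite feature values", call. = FALSE)
  if (!identical(colnames(presence), colnames(background)))
    stop("presence and background feature columns differ", call. = FALSE)
  m <- nrow(presence); B <- nrow(background); J <- ncol(presence)
  fbar <- colMeans(presence)
  cls <- attr(presence, "feature_class")
  fvars <- attr(presence, "feature_vars")
  # matrix subsetting drops attributes; recover them from the encoded names
  if (is.null(cls))
    cls <- stats::setNames(substr(colnames(presence), 1, 1), colnames(presence))
  if (is.null(fvars)) {
    fvars <- lapply(strsplit(sub("^[A-Za-z]+_", "", colnames(presence)), "_"),
                    function(parts) parts[!grepl("^[0-9.]+$", parts)])
    names(fvars) <- colnames(presence)
  }
  sj <- pmax(apply(presence, 2, stats::sd), 1e-4)
  if (m == 1) sj <- rep(1e-4, J)
  beta <- rm * vapply(seq_len(J), function(j) base_penalty(cls[[j]], m),
                      numeric(1)) * sj / sqrt(m)
  lambda <- rep(0, J)
  eta <- rep(0, B)                      # background linear predictor
  gain_of <- function(eta_vec, lam) {
    mx <- max(eta_vec)
    sum(fbar * lam) - (mx + log(mean(exp(eta_vec - mx)))) - sum(beta * abs(lam))
  }
  gain <- 0
  gain_trace <- numeric(0)
  credit <- stats::setNames(rep(0, J), colnames(presence))
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    gain_start <- gain
    mx <- max(eta)
    w <- exp(eta - mx); w <- w / sum(w)
    for (j in seq_len(J)) {
      fj <- background[, j]
      Ef <- sum(w * fj)
      grad <- fbar[j] - Ef
      hess <- sum(w * fj^2) - Ef^2
      if (hess < 1e-10) next
      u <- lambda[j] + grad / hess
      new_l <- sign(u) * max(0, abs(u) - beta[j] / hess)
      if (new_l == lambda[j]) next
      step <- new_l - lambda[j]
      # backtracking to guarantee monotone gain
      repeat {
        cand_l <- lambda[j] + step
        cand_eta <- eta + step * fj
        lam2 <- lambda; lam2[j] <- cand_l
        g2 <- gain_of(cand_eta, lam2)
        if (g2 >= gain - 1e-12 || abs(step) < 1e-12) break
        step <- step / 2
      }
      if (abs(step) < 1e-12) next
      if (g2 > gain) credit[j] <- credit[j] + (g2 - gain)
      lambda[j] <- lambda[j] + step
      eta <- eta + step * fj
      gain <- g2
      mx <- max(eta)
      w <- exp(eta - mx); w <- w / sum(w)
    }
    gain_trace <- c(gain_trace, gain)
    if (gain - gain_start < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("coordinate descent did not converge in %d sweeps", max_sweeps))
  mx <- max(eta)
  q <- exp(eta - mx); q <- q / sum(q)
  entropy_H <- -sum(ifelse(q > 0, q * log(q), 0))
  structure(list(
    lambdas = stats::setNames(lambda, colnames(presence)),
    feature_class = cls, feature_vars = fvars,
    Z = sum(exp(eta)), entropy_H = entropy_H, rm = rm,
    training_gain = gain, gain_trace = gain_trace, credit = credit,
    n_presence = m, n_background = B), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d features (%d nonzero), rm = %g, gain = %.4f, H = %.3f\n",
              length(x$lambdas), sum(x$lambdas != 0), x$rm, x$training_gain,
              x$entropy_H))
  invisible(x)
}

# Raw probabilities of arbitrary feature rows under the model's background
# normalization (raw sums to 1 over the background rows themselves).
raw_scores <- function(model, features) {
  exp(as.vector(features %*% model$lambdas)) / model$Z
}

#' Logistic output of a maximum-entropy model
#'
#' `logistic = c * raw / (1 + c * raw)` with `c = exp(H)`, H the entropy of
#' the raw background distribution. A completely uninformative model (all
#' coefficients zero) scores exactly 0.5 everywhere.
#'
#' @param model A `maxent_model`.
#' @param features Feature matrix rows to score.
#' @return Numeric vector in (0, 1).
#' @export
logistic_scores <- function(model, features) {
  cr <- exp(model$entropy_H) * raw_scores(model, features)
  cr / (1 + cr)
}

#' Predict a suitability raster from a fitted model
#'
#' Expands the stack's cell values with the model's feature specification and
#' scores every valid cell.
#'
#' @param object A `maxent_model` carrying attribute `"feature_spec"` (set by
#'   [fit_maxent_on()] / [tune_maxent()]) or a `feature_spec` passed via
#'   `fspec`.
#' @param stack An [env_stack()] with all model variables.
#' @param output `"logistic"` (default) or `"raw"`.
#' @param fspec Optional [feature_spec()] override.
#' @param ... Unused.
#' @return An [nd_raster()] of suitabilities.
#' @export
predict.maxent_model <- function(object, stack, output = c("logistic", "raw"),
                                 fspec = attr(object, "feature_spec"), ...) {
  output <- match.arg(output)
  if (is.null(fspec)) stop("no feature_spec available for prediction", call. = FALSE)
  miss <- setdiff(fspec$variables, names(stack$layers))
  if (length(miss))
    stop(sprintf("stack lacks model variable(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  spec <- stack$spec
  vals <- sapply(fspec$variables, function(v) as.vector(stack$layers[[v]]$values))
  vals <- as.data.frame(matrix(vals, ncol = length(fspec$variables),
                               dimnames = list(NULL, fspec$variables)))
  ok <- stats::complete.cases(vals)
  out <- rep(NA_real_, nrow(vals))
  if (any(ok)) {
    f <- build_features(fspec, vals[ok, , drop = FALSE])
    out[ok] <- if (output == "raw") raw_scores(object, f)
               else logistic_scores(object, f)
  }
  nd_raster(matrix(out, spec$nrows, spec$ncols), spec)
}

#' Rank-based AUC with the field's performance banding
#'
#' Mann-Whitney AUC: probability that a random presence score exceeds a random
#' background score, ties counted one half. Bands: `<= 0.7` poor, `(0.7, 0.9]`
#' moderate, `> 0.9` high performance.
#'
#' @param scores_presence,scores_background Non-empty numeric score vectors.
#' @return Scalar AUC with attribute `"band"`.
#' @export
auc <- function(scores_presence, scores_background) {
  if (!length(scores_presence) || !length(scores_background))
    stop("both score vectors must be non-empty", call. = FALSE)
  pooled <- c(scores_presence, scores_background)
  if (length(unique(pooled)) == 1L) {
    warning("constant scores: AUC = 0.5")
    a <- 0.5
  } else {
    r <- rank(pooled)
    m <- length(scores_presence); n <- length(scores_background)
    a <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  }
  attr(a, "band") <- auc_band(a)
  a
}

#' @rdname auc
#' @param x AUC value.
#' @export
auc_band <- function(x) {
  if (x > 0.9) "high performance"
  else if (x > 0.7) "moderate performance"
  else "poor performance"
}

#' Sample-size-corrected AIC for a fitted model
#'
#' `k` = number of nonzero coefficients; `lnL` is the log-likelihood of the
#' occurrence rows under the raw distribution renormalized over all cells;
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)`, flagged invalid when `k >= n - 1`.
#'
#' @param model A `maxent_model`.
#' @param occ_features Feature rows of the occurrences.
#' @param cell_features Feature rows of all cells (the normalization domain).
#' @return List `k`, `lnL`, `aicc`, `valid`.
#' @export
aicc <- function(model, occ_features, cell_features) {
  n <- nrow(occ_features)
  if (n < 2) stop("need >= 2 occurrence rows for AICc", call. = FALSE)
  k <- sum(model$lambdas != 0)
  eta_occ <- as.vector(occ_features %*% model$lambdas)
  eta_all <- as.vector(cell_features %*% model$lambdas)
  mx <- max(eta_all)
  logZ <- mx + log(sum(exp(eta_all - mx)))
  lnL <- sum(eta_occ - logZ)
  if (k >= n - 1)
    return(list(k = k, lnL = lnL, aicc = NA_real_, valid = FALSE))
  list(k = k, lnL = lnL,
       aicc = 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1), valid = TRUE)
}
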