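#' Extract environmental values at occurrence points
#'
#' Nearest-cell lookup: each point takes the value of the cell containing it
#' under the half-open cell convention. Points outside the grid extent, and
#' rows hitting nodata in any layer, are excluded; their counts are attached
#' as attributes `"n_outside"` and `"n_nodata"`.
#'
#' @param stack An [env_stack()].
#' @param occ An `occurrence_set`.
#' @return Data frame of layer values (one column per layer, one row per
#'   retained point), with attribute `"rows"` giving the retained input rows.
#' @export
extract_at_points <- function(stack, occ) {
  idx <- cell_index(stack$spec, occ$lon, occ$lat)
  inside <- !is.na(idx$row)
  vals <- sapply(stack$layers, function(ly)
    ifelse(inside, ly$values[cbind(idx$row, idx$col)], NA_real_))
  vals <- matrix(vals, nrow = nrow(occ),
                 dimnames = list(NULL, names(stack$layers)))
  complete <- inside & !apply(is.na(vals), 1, any)
  out <- as.data.frame(vals[complete, , drop = FALSE])
  attr(out, "rows") <- which(complete)
  attr(out, "n_outside") <- sum(!inside)
  attr(out, "n_nodata") <- sum(inside) - sum(complete)
  out
}

#' Remove variables with zero model contribution
#'
#' @param vars Character vector of candidate variable names.
#' @param contributions Named numeric vector or list of percent contributions
#'   covering all of `vars`.
#' @return Character vector of variables with contribution > 0.
#' @export
drop_zero_contribution <- function(vars, contributions) {
  contributions <- unlist(contributions)
  miss <- setdiff(vars, names(contributions))
  if (length(miss))
    stop(sprintf("contributions missing for: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  kept <- vars[contributions[vars] > 0]
  if (!length(kept)) warning("all variables have zero contribution")
  kept
}

#' Correlation-based variable filter with an ecological-importance override
#'
#' Greedy pairwise elimination: correlated pairs with `|r| >= threshold` are
#' visited in order of descending `|r|` (ties by variable name); in each pair
#' still fully retained, the member with the lower model contribution is
#' removed — unless it is listed in `keep`, in which case its partner is
#' removed instead. Pairs whose members are both in `keep` survive intact.
#'
#' @param table Data frame of variable values at occurrence points (>= 3 rows).
#' @param threshold Absolute Pearson correlation threshold in `(0, 1]`
#'   (default 0.80).
#' @param keep Character vector of variables protected on ecological grounds.
#' @param rank Named numeric vector of percent contributions used to decide
#'   which pair member is dropped; variables missing from `rank` count as 0.
#' @return Character vector of retained variable names (subset of the input
#'   columns, original order). Attribute `"dropped"` lists removals with the
#'   pair and correlation responsible.
#' @export
pearson_filter <- function(table, threshold = 0.80, keep = character(0),
                           rank = numeric(0)) {
  if (nrow(table) < 3) stop("need >= 3 rows for correlation filtering", call. = FALSE)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]", call. = FALSE)
  vars <- colnames(table)
  bad <- setdiff(keep, vars)
  if (length(bad))
    stop(sprintf("keep names not in table: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  cm <- stats::cor(table)
  pairs <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
  if (nrow(pairs)) {
    pr <- data.frame(a = vars[pairs[, 1]], b = vars[pairs[, 2]],
                     r = cm[pairs], stringsAsFactors = FALSE)
    pr <- pr[order(-abs(pr$r), pr$a, pr$b), ]
  } else pr <- NULL
  score <- function(v) if (v %in% names(rank)) unname(rank[v]) else 0
  alive <- vars
  dropped <- NULL
  if (!is.null(pr)) for (k in seq_len(nrow(pr))) {
    a <- pr$a[k]; b <- pr$b[k]
    if (!(a %in% alive) || !(b %in% alive)) next
    in_keep <- c(a, b) %in% keep
    victim <- if (all(in_keep)) NA_character_
      else if (in_keep[1]) b
      else if (in_keep[2]) a
      else if (score(a) < score(b)) a else b
    if (is.na(victim)) next
    alive <- setdiff(alive, victim)
    dropped <- rbind(dropped, data.frame(dropped = victim,
                                         partner = setdiff(c(a, b), victim),
                                         r = pr$r[k]))
  }
  out <- vars[vars %in% alive]
  attr(out, "dropped") <- dropped
  attr(out, "correlation") <- cm
  out
}

#' Combine per-replicate contribution tables
#'
#' Replicate runs of the suitability model each report percent contributions;
#' they are combined by arithmetic mean per variable.
#'
#' @param reps List of named numeric vectors (one per replicate).
#' @return Named numeric vector of mean contributions.
#' @export
mean_contributions <- function(reps) {
  vars <- unique(unlist(lapply(reps, names)))
  out <- vapply(vars, function(v)
    mean(vapply(reps, function(r) if (v %in% names(r)) r[[v]] else 0, numeric(1))),
    numeric(1))
  stats::setNames(out, vars)
}
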