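#' Feature specification for the maximum-entropy model
#'
#' Declares the feature classes expanded from each environmental variable and
#' stores the background min/max normalizers all features are scaled with.
#' Classes: `L` linear (min-max scaled to `[0,1]`), `Q` quadratic (square of
#' L), `P` products of distinct L pairs, `H` forward and reverse hinges at
#' evenly spaced interior knots, `T` threshold (step) indicators at the same
#' knots. The menu follows the usual convention that `Q` and `P` accompany
#' `L` (pure `H` is the only L-free combination used).
#'
#' @param classes Character vector, subset of `c("L","Q","P","H","T")`, or a
#'   compact string such as `"LQH"`.
#' @param variables Character vector of variable names.
#' @param background Data frame of background values (used for min/max).
#' @param hinge_knots Interior knots per variable per hinge direction
#'   (default 20; >= 2 required when `H` or `T` is present).
#' @return Object of class `feature_spec`.
#' @export
feature_spec <- function(classes, variables, background, hinge_knots = 20) {
  if (length(classes) == 1 && nchar(classes) > 1)
    classes <- strsplit(classes, "")[[1]]
  classes <- toupper(classes)
  bad <- setdiff(classes, c("L", "Q", "P", "H", "T"))
  if (length(bad)) stop(sprintf("unknown feature class: %s", bad[1]), call. = FALSE)
  if (any(c("Q", "P") %in% classes) && !("L" %in% classes))
    stop("Q and P feature classes require L", call. = FALSE)
  if (any(c("H", "T") %in% classes) && hinge_knots < 2)
    stop("H/T features need hinge_knots >= 2", call. = FALSE)
  miss <- setdiff(variables, colnames(background))
  if (length(miss))
    stop(sprintf("background lacks variable(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  rng <- lapply(variables, function(v)
    range(background[[v]], na.rm = TRUE))
  names(rng) <- variables
  structure(list(classes = classes, variables = variables, range = rng,
                 hinge_knots = hinge_knots), class = "feature_spec")
}

#' Expand a variable table into the model's feature matrix
#'
#' Columns are ordered deterministically: all L, then Q, then P (pairs in
#' variable order), then H (per variable: forward knots then reverse knots),
#' then T. All features lie in `[0, 1]`; raw values are clamped to the
#' background range before scaling. Constant variables contribute an L column
#' of zeros and have their Q/H/T features dropped with a warning.
#'
#' @param spec A [feature_spec()].
#' @param table Data frame containing the spec's variables.
#' @return Numeric matrix with named columns; attribute `"feature_vars"` maps
#'   each column to the underlying variable(s).
#' @export
build_features <- function(spec, table) {
  stopifnot(inherits(spec, "feature_spec"))
  vars <- spec$variables
  n <- nrow(table)
  const <- vapply(vars, function(v) diff(spec$range[[v]]) == 0, logical(1))
  if (any(const))
    warning(sprintf("constant variable(s) %s: only a zero L column is emitted",
                    paste(vars[const], collapse = ", ")))
  L <- sapply(vars, function(v) {
    r <- spec$range[[v]]
    if (diff(r) == 0) return(rep(0, n))
    pmin(pmax((table[[v]] - r[1]) / (r[2] - r[1]), 0), 1)
  })
  L <- matrix(L, nrow = n, dimnames = list(NULL, vars))
  cols <- list(); cn <- character(0); fv <- list()
  add <- function(x, name, varnames) {
    cols[[length(cols) + 1L]] <<- x
    cn[length(cn) + 1L] <<- name
    fv[[length(fv) + 1L]] <<- varnames
  }
  has_L <- "L" %in% spec$classes || any(c("Q", "P") %in% spec$classes)
  if (has_L) for (v in vars) add(L[, v], paste0("L_", v), v)
  if ("Q" %in% spec$classes) for (v in vars[!const])
    add(L[, v]^2, paste0("Q_", v), v)
  if ("P" %in% spec$classes && length(vars) >= 2) {
    for (i in seq_len(length(vars) - 1)) for (j in (i + 1):length(vars))
      add(L[, vars[i]] * L[, vars[j]],
          paste0("P_", vars[i], "_", vars[j]), c(vars[i], vars[j]))
  }
  knot_pos <- function() seq_len(spec$hinge_knots) / (spec$hinge_knots + 1)
  if ("H" %in% spec$classes) for (v in vars[!const]) {
    for (k in knot_pos())
      add(pmax(0, (L[, v] - k) / (1 - k)), sprintf("Hf_%s_%.4f", v, k), v)
    for (k in knot_pos())
      add(pmax(0, (k - L[, v]) / k), sprintf("Hr_%s_%.4f", v, k), v)
  }
  if ("T" %in% spec$classes) for (v in vars[!const])
    for (k in knot_pos())
      add(as.numeric(L[, v] >= k), sprintf("T_%s_%.4f", v, k), v)
  m <- do.call(cbind, cols)
  colnames(m) <- cn
  attr(m, "feature_vars") <- stats::setNames(fv, cn)
  attr(m, "feature_class") <- stats::setNames(substr(cn, 1, 1), cn)
  m
}

# Row-subset a feature matrix while keeping its feature metadata (plain
# matrix subsetting drops attributes).
subset_features <- function(m, rows) {
  out <- m[rows, , drop = FALSE]
  attr(out, "feature_vars") <- attr(m, "feature_vars")
  attr(out, "feature_class") <- attr(m, "feature_class")
  out
}
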