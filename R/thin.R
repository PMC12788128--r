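#' Spatial thinning of occurrence records on a grid
#'
#' Keeps at most one record per grid cell, the canonical guard against
#' within-cell pseudo-replication before fitting a suitability model. At
#' `level = "species"` a cell may retain one record of each species; at
#' `level = "genus"` species labels are ignored and one record per cell
#' survives. Within a cell the first record in input order is kept
#' (deterministic and auditable). Points outside the grid extent are dropped
#' with a warning giving their count.
#'
#' @param occ An `occurrence_set`.
#' @param spec A [grid_spec()] defining the thinning cells.
#' @param level `"species"` or `"genus"`.
#' @return A thinned `occurrence_set` (a subset of the input, in input order).
#' @export
thin_occurrences <- function(occ, spec, level = c("species", "genus")) {
  level <- match.arg(level)
  if (nrow(occ) == 0) stop("cannot thin an empty occurrence set", call. = FALSE)
  idx <- cell_index(spec, occ$lon, occ$lat)
  outside <- is.na(idx$row)
  if (any(outside))
    warning(sprintf("%d point(s) outside the grid extent were dropped", sum(outside)))
  keep_rows <- which(!outside)
  key <- paste(idx$row[keep_rows], idx$col[keep_rows])
  if (level == "species") key <- paste(occ$species[keep_rows], key)
  retained <- keep_rows[!duplicated(key)]
  out <- occ[retained, , drop = FALSE]
  class(out) <- c("occurrence_set", "data.frame")
  rownames(out) <- NULL
  out
}

#' Before/after bookkeeping for spatial thinning
#'
#' Per-species record counts before and after thinning, with a totals row.
#' Species absent after thinning are listed with count 0.
#'
#' @param before,after `occurrence_set`s; `after` must be a subset of `before`.
#' @return Data frame with columns `species`, `n_before`, `n_after`.
#' @export
thinning_report <- function(before, after) {
  sp <- unique(before$species)
  tab_b <- table(factor(before$species, levels = sp))
  tab_a <- table(factor(after$species, levels = sp))
  out <- data.frame(species = sp,
                    n_before = as.integer(tab_b),
                    n_after = as.integer(tab_a),
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(species = "Total",
                        n_before = nrow(before), n_after = nrow(after)))
}
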