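#' Global MART1-adjusted proliferation index
#'
#' Number of PHH3/MART1-positive cells divided by the MART1-verified tumor
#' area (cells/mm^2).  Zero-area handling is a tri-state: a value when the
#' area is positive, 0 when both count and area are zero (flagged
#' `undefined`), and an error when cells were detected with no tumor area
#' (an internal inconsistency that signals a detection bug).
#'
#' @param cells a `cell_set` or an integer count.
#' @param tumor a `tumor_mask` or an area in mm^2.
#' @return list with `count`, `area_mm2`, `index` (cells/mm^2), `status`
#'   in `ok`/`undefined`.
#' @export
global_index <- function(cells, tumor) {
  count <- if (inherits(cells, "cell_set")) sum(cells$positive)
           else as.integer(cells)
  area <- if (inherits(tumor, "tumor_mask")) tumor$area_mm2 else as.numeric(tumor)
  if (area < 0) stop("tumor area must be >= 0")
  if (area == 0) {
    if (count > 0)
      stop("inconsistency: ", count, " positive cells with zero tumor area")
    return(list(count = 0L, area_mm2 = 0, index = NA_real_,
                status = "undefined"))
  }
  list(count = count, area_mm2 = area, index = count / area, status = "ok")
}

#' Hot-spot count and MART1-adjusted hot-spot index
#'
#' The hot-spot index is reported both as the raw number of positive cells
#' within the 1-mm^2 square and as that count divided by the
#' MART1-verified tumor area intersected with the square (minor regions
#' outside the tumor are thereby subtracted from the reference area).
#'
#' @param cells a `cell_set`.
#' @param tumor a `tumor_mask`.
#' @param hotspot a `hot_spot` from [select_hotspot()].
#' @param exclusions polygons excluded from the count.
#' @return list with `count`, `area_mm2` (tumor area within the square),
#'   `adjusted_index` (cells/mm^2), `status`.
#' @export
hotspot_indices <- function(cells, tumor, hotspot, exclusions = NULL) {
  if (is.null(hotspot)) stop("no hot spot: no positive cells to anchor one")
  count <- count_in_square(cells, hotspot$square, exclusions)
  s <- tumor$um_per_px
  nrp <- nrow(tumor$mask); ncp <- ncol(tumor$mask)
  j0 <- max(1L, floor(hotspot$square[1] / s) + 1L)
  j1 <- min(ncp, ceiling(hotspot$square[3] / s))
  i0 <- max(1L, floor(hotspot$square[2] / s) + 1L)
  i1 <- min(nrp, ceiling(hotspot$square[4] / s))
  area <- if (j0 > j1 || i0 > i1) 0
          else sum(tumor$mask[i0:i1, j0:j1]) * s^2 / 1e6
  if (area == 0) {
    if (count > 0)
      stop("inconsistency: ", count,
           " positive cells in the square with zero MART1 area")
    return(list(count = 0L, area_mm2 = 0, adjusted_index = NA_real_,
                status = "undefined"))
  }
  list(count = count, area_mm2 = area, adjusted_index = count / area,
       status = "ok")
}

#' Dichotomize an index at a cut-off
#'
#' Pure threshold function used to split cases into low/high proliferation
#' groups.  Rule `"gt"` marks high strictly above the cut-off (e.g.
#' "<= 2.0 vs. > 2.0"); rule `"ge"` marks high at or above it (e.g.
#' "0 vs. >= 1").
#'
#' @param index numeric value(s).
#' @param cutoff finite cut-off.
#' @param rule `"gt"` or `"ge"`.
#' @return factor with levels `low`, `high`.
#' @export
dichotomize <- function(index, cutoff, rule = c("gt", "ge")) {
  rule <- match.arg(rule)
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  high <- if (rule == "gt") index > cutoff else index >= cutoff
  factor(ifelse(high, "high", "low"), levels = c("low", "high"))
}

#' Named cut-off presets for the shipped dichotomies
#'
#' Median-based cut-offs for each quantification route: manual hot-spot
#' count (0 vs >= 1), manual MART1-adjusted hot-spot (> 7.7/mm^2) and
#' global (> 3.3/mm^2) indices, automated hot-spot count in the manual
#' hot spot (0 vs >= 1), automated hot-spot count (> 2.0), automated
#' MART1-adjusted hot-spot (> 14/mm^2) and global (> 4.0/mm^2) indices.
#'
#' @return data.frame with `name`, `cutoff`, `rule`.
#' @export
index_cutoffs <- function() {
  data.frame(
    name = c("manual_hotspot_count", "manual_hotspot_adjusted",
             "manual_global_adjusted", "auto_count_manual_hotspot",
             "auto_hotspot_count", "auto_hotspot_adjusted",
             "auto_global_adjusted"),
    cutoff = c(1, 7.7, 3.3, 1, 2.0, 14, 4.0),
    rule = c("ge", "gt", "gt", "ge", "gt", "gt", "gt"),
    stringsAsFactors = FALSE)
}

#' Assemble the full proliferation result
#'
#' @param cells a `cell_set`.
#' @param tumor a `tumor_mask`.
#' @param hotspot a `hot_spot`, or `NULL` for the no-hot-spot outcome.
#' @param exclusions polygons excluded from counting.
#' @param config the `ms_config` used (for the provenance hash).
#' @return `proliferation_result` list: global and hot-spot counts, areas
#'   and indices, the applied cut-offs with their dichotomies, and the
#'   config hash.
#' @export
proliferation_result <- function(cells, tumor, hotspot, exclusions = NULL,
                                 config = default_config()) {
  glob <- global_index(cells, tumor)
  hs <- if (!is.null(hotspot)) hotspot_indices(cells, tumor, hotspot, exclusions)
        else list(count = 0L, area_mm2 = NA_real_, adjusted_index = NA_real_,
                  status = "no_hotspot")
  cuts <- index_cutoffs()
  vals <- c(auto_hotspot_count = hs$count,
            auto_hotspot_adjusted = hs$adjusted_index,
            auto_global_adjusted = glob$index)
  dich <- lapply(names(vals), function(nm) {
    row <- cuts[cuts$name == nm, ]
    v <- vals[[nm]]
    if (is.na(v)) NA_character_
    else as.character(dichotomize(v, row$cutoff, row$rule))
  })
  names(dich) <- names(vals)
  structure(list(
    global_count = glob$count, global_area_mm2 = glob$area_mm2,
    global_index = glob$index, global_status = glob$status,
    hotspot = if (is.null(hotspot)) NULL else
      list(center = as.numeric(hotspot$center),
           square = as.numeric(hotspot$square),
           peak_intensity = hotspot$peak_intensity),
    hotspot_count = hs$count, hotspot_area_mm2 = hs$area_mm2,
    hotspot_adjusted_index = hs$adjusted_index, hotspot_status = hs$status,
    dichotomies = dich, config_hash = config_hash(config)),
    class = "proliferation_result")
}

#' @export
print.proliferation_result <- function(x, ...) {
  cat("<proliferation_result>\n")
  cat(sprintf("  global: %d cells / %.4g mm^2 = %s cells/mm^2\n",
              x$global_count, x$global_area_mm2,
              if (is.na(x$global_index)) "NA" else sprintf("%.3g", x$global_index)))
  if (identical(x$hotspot_status, "no_hotspot")) {
    cat("  hot spot: none (no positive cells)\n")
  } else {
    cat(sprintf("  hot spot: %d cells / %.4g mm^2 = %s cells/mm^2\n",
                x$hotspot_count, x$hotspot_area_mm2,
                if (is.na(x$hotspot_adjusted_index)) "NA"
                else sprintf("%.3g", x$hotspot_adjusted_index)))
  }
  invisible(x)
}
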