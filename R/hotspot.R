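#' Build the circle-overlap object heat map
#'
#' A circle of radius `radius_um` (default 200 um) is conceptually centred
#' on every positive cell; every point inside a circle accumulates 1.
#' Equivalently, the heat-map intensity at a grid point is the number of
#' positive cells within `radius_um` of it (boundary inclusive).  The grid
#' spans the bounding box of the analysis domain at `grid_step_um`
#' spacing.
#'
#' @param cells a `cell_set` (its positive cells are used) or an n x 2
#'   centroid matrix.
#' @param domain polygon (um) of the analysis domain, or a bounding box
#'   `c(xmin, ymin, xmax, ymax)`.
#' @param radius_um circle radius, > 0.
#' @param grid_step_um grid spacing, > 0.
#' @return `heat_map`: list with integer matrix `intensity` (rows = y),
#'   grid coordinates `xs`, `ys` (um), `radius_um`, `domain`.
#' @export
build_heatmap <- function(cells, domain, radius_um = 200, grid_step_um = 10) {
  if (radius_um <= 0 || grid_step_um <= 0)
    stop("radius_um and grid_step_um must be positive")
  cen <- if (inherits(cells, "cell_set")) positive_centroids(cells)
         else as.matrix(cells)
  dom <- normalize_domain(domain)
  if (dom$area <= 0) stop("empty analysis domain")
  xs <- seq(dom$bbox[1], dom$bbox[3], by = grid_step_um)
  ys <- seq(dom$bbox[2], dom$bbox[4], by = grid_step_um)
  inten <- cpp_heatmap_counts(xs, ys,
                              if (nrow(cen)) cen[, 1] else numeric(0),
                              if (nrow(cen)) cen[, 2] else numeric(0),
                              radius_um)
  structure(list(intensity = inten, xs = xs, ys = ys,
                 radius_um = radius_um, grid_step_um = grid_step_um,
                 domain = dom, cells = cen), class = "heat_map")
}

normalize_domain <- function(domain) {
  if (is.matrix(domain) || is.data.frame(domain)) {
    p <- as_poly(domain)
    bb <- c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))
    list(poly = p, bbox = bb, area = poly_area(p))
  } else if (is.numeric(domain) && length(domain) == 4) {
    list(poly = NULL, bbox = domain,
         area = (domain[3] - domain[1]) * (domain[4] - domain[2]))
  } else stop("domain must be a polygon or c(xmin, ymin, xmax, ymax)")
}

#' @export
print.heat_map <- function(x, ...) {
  cat(sprintf("<heat_map> %d x %d grid @ %g um, radius %g um, peak %d\n",
              length(x$ys), length(x$xs), x$grid_step_um, x$radius_um,
              max(x$intensity)))
  invisible(x)
}

#' Select the hottest hot spot
#'
#' The hot-spot centre is the grid position with the most circle overlaps
#' (the heat-map argmax).  Ties are resolved deterministically: the
#' largest 8-connected component of maximal eligible grid points wins and
#' its centroid is used; among equal-sized components the one whose first
#' point comes earliest in scan order (by y, then x) wins.  The centre is
#' encompassed by an axis-aligned square of side `square_side_um`
#' (1 mm^2 by default).  With `selector = "square"` the centre maximises
#' the positive-cell count of the square itself (placement-oracle mode)
#' instead of the circle-overlap intensity.
#'
#' @param heatmap a `heat_map`.
#' @param exclusions list of polygons; grid points inside any are
#'   ineligible as centres.
#' @param square_side_um reference square side (um).
#' @param selector `"peak"` (circle-overlap argmax, primary) or
#'   `"square"` (exhaustive square-placement maximiser).
#' @return `hot_spot`: list with `center` (x, y um), `square`
#'   `c(xmin, ymin, xmax, ymax)`, `peak_intensity`, `count`; or `NULL`
#'   when there is no positive cell (the distinguished "no hot spot"
#'   outcome).
#' @export
select_hotspot <- function(heatmap, exclusions = NULL,
                           square_side_um = 1000, selector = "peak") {
  if (max(heatmap$intensity) == 0 || nrow(heatmap$cells) == 0) return(NULL)
  elig <- eligibility(heatmap, exclusions)
  if (!any(elig)) return(NULL)
  score <- if (selector == "square") {
    square_counts(heatmap, square_side_um, exclusions)
  } else heatmap$intensity
  score[!elig] <- -1L
  peak <- max(score)
  if (peak < 0) return(NULL)
  maxmask <- score == peak
  if (selector == "square") {
    ## oracle mode: the centre is an argmax grid point itself (scan-order
    ## first), so the reported count equals the exhaustive placement max
    w <- which(maxmask)
    i <- ((w - 1L) %% nrow(maxmask)) + 1L
    j <- ((w - 1L) %/% nrow(maxmask)) + 1L
    k <- which.min((i - 1L) * ncol(maxmask) + j)
    center <- c(x = heatmap$xs[j[k]], y = heatmap$ys[i[k]])
    half <- square_side_um / 2
    square <- c(center[1] - half, center[2] - half,
                center[1] + half, center[2] + half)
    return(structure(list(center = center, square = unname(square),
                          peak_intensity = heatmap$intensity[i[k], j[k]],
                          count = count_in_square(heatmap$cells, square,
                                                  exclusions),
                          selector = selector), class = "hot_spot"))
  }
  comp <- cpp_label(maxmask)
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    ## earliest first member in scan order (row-major by y then x)
    first <- vapply(best, function(id) {
      w <- which(comp == id)
      i <- ((w - 1L) %% nrow(comp)) + 1L
      j <- ((w - 1L) %/% nrow(comp)) + 1L
      min((i - 1L) * ncol(comp) + j)
    }, numeric(1))
    best <- best[which.min(first)]
  }
  w <- which(comp == best[1])
  i <- ((w - 1L) %% nrow(comp)) + 1L
  j <- ((w - 1L) %/% nrow(comp)) + 1L
  center <- c(x = mean(heatmap$xs[j]), y = mean(heatmap$ys[i]))
  half <- square_side_um / 2
  square <- c(center[1] - half, center[2] - half,
              center[1] + half, center[2] + half)
  cnt <- count_in_square(heatmap$cells, square, exclusions)
  structure(list(center = center, square = unname(square),
                 peak_intensity = max(heatmap$intensity[cbind(i, j)]),
                 count = cnt, selector = selector), class = "hot_spot")
}

eligibility <- function(heatmap, exclusions) {
  nx <- length(heatmap$xs); ny <- length(heatmap$ys)
  g <- expand.grid(y = heatmap$ys, x = heatmap$xs)
  ok <- rep(TRUE, nrow(g))
  if (!is.null(heatmap$domain$poly))
    ok <- points_in_poly(g$x, g$y, heatmap$domain$poly)
  for (ex in exclusions %||% list())
    ok <- ok & !points_in_poly(g$x, g$y, ex)
  matrix(ok, ny, nx)
}

## Count of positive cells in the square centred at each grid point.
square_counts <- function(heatmap, square_side_um, exclusions) {
  half <- square_side_um / 2
  cen <- heatmap$cells
  ny <- length(heatmap$ys); nx <- length(heatmap$xs)
  out <- matrix(0L, ny, nx)
  keep <- rep(TRUE, nrow(cen))
  for (ex in exclusions %||% list())
    keep <- keep & !points_in_poly(cen[, 1], cen[, 2], ex)
  cen <- cen[keep, , drop = FALSE]
  for (c_i in seq_len(nrow(cen))) {
    jx <- which(heatmap$xs > cen[c_i, 1] - half & heatmap$xs <= cen[c_i, 1] + half)
    iy <- which(heatmap$ys > cen[c_i, 2] - half & heatmap$ys <= cen[c_i, 2] + half)
    out[iy, jx] <- out[iy, jx] + 1L
  }
  out
}

#' @export
print.hot_spot <- function(x, ...) {
  cat(sprintf(
    "<hot_spot> center (%.1f, %.1f) um, peak intensity %d, %d cells in square\n",
    x$center[1], x$center[2], x$peak_intensity, x$count))
  invisible(x)
}

#' Count positive cells inside a square
#'
#' The square is half-open: a centroid on the left/top edge counts, one on
#' the right/bottom edge does not.
#'
#' @param cells a `cell_set` or n x 2 centroid matrix.
#' @param square `c(xmin, ymin, xmax, ymax)` in um.
#' @param exclusions list of polygons whose interior is not counted.
#' @return integer count.
#' @export
count_in_square <- function(cells, square, exclusions = NULL) {
  cen <- if (inherits(cells, "cell_set")) positive_centroids(cells)
         else as.matrix(cells)
  if (nrow(cen) == 0) return(0L)
  inside <- cen[, 1] >= square[1] & cen[, 1] < square[3] &
            cen[, 2] >= square[2] & cen[, 2] < square[4]
  for (ex in exclusions %||% list())
    inside <- inside & !points_in_poly(cen[, 1], cen[, 2], ex)
  sum(inside)
}

#' Categorize the overlap of two hot-spot squares
#'
#' Based on the absolute distances between the centre coordinates of the
#' two 1-mm^2 squares, combined by their maximum (Chebyshev distance), in
#' mm: perfect overlap below 0.10, mayor overlap in \[0.10, 0.75), minor
#' overlap in \[0.75, 1.0\], no overlap above 1.0 (at which point the
#' squares are geometrically disjoint).
#'
#' @param center_a,center_b centres (x, y); micrometres by default.
#' @param units `"um"` or `"mm"`.
#' @return `overlap_result`: list with `dx_mm`, `dy_mm`, `category` in
#'   `PERFECT, MAYOR, MINOR, NONE`.
#' @export
categorize_overlap <- function(center_a, center_b, units = c("um", "mm")) {
  units <- match.arg(units)
  f <- if (units == "um") 1e-3 else 1
  dx <- abs(center_a[1] - center_b[1]) * f
  dy <- abs(center_a[2] - center_b[2]) * f
  d <- max(dx, dy)
  category <- if (d < 0.10) "PERFECT"
              else if (d < 0.75) "MAYOR"
              else if (d <= 1.0) "MINOR"
              else "NONE"
  structure(list(dx_mm = unname(dx), dy_mm = unname(dy), category = category),
            class = "overlap_result")
}
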