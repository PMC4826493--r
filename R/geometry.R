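## Planar geometry helpers on simple polygons given as two-column matrices
## (x, y) in micrometres, vertices in order, ring implicitly closed.

as_poly <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2 || nrow(p) < 3) stop("polygon needs >= 3 (x, y) vertices")
  storage.mode(p) <- "double"
  ## drop an explicit closing vertex
  if (all(p[1, ] == p[nrow(p), ]) && nrow(p) > 3) p <- p[-nrow(p), , drop = FALSE]
  p
}

#' Signed/absolute area of a simple polygon (shoelace formula)
#' @param poly two-column matrix of vertices (x, y).
#' @return area in squared input units.
#' @export
poly_area <- function(poly) {
  p <- as_poly(poly)
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:nrow(p), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Test points for polygon membership (even-odd rule)
#' @param x,y point coordinates.
#' @param poly two-column vertex matrix.
#' @return logical vector.
#' @export
points_in_poly <- function(x, y, poly) {
  p <- as_poly(poly)
  cpp_points_in_poly(as.numeric(x), as.numeric(y), p[, 1], p[, 2])
}

## Minimum distance from points to the polygon boundary (segments).
dist_to_poly_edge <- function(x, y, poly) {
  p <- as_poly(poly)
  n <- nrow(p)
  d2 <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- p[i, 1]; ay <- p[i, 2]
    bx <- p[j, 1]; by <- p[j, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / L2))
    dd <- (x - (ax + t * vx))^2 + (y - (ay + t * vy))^2
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}

## Simple-polygon check: no two non-adjacent edges intersect.
poly_is_simple <- function(poly) {
  p <- as_poly(poly)
  n <- nrow(p)
  seg <- function(i) {
    j <- if (i == n) 1L else i + 1L
    rbind(p[i, ], p[j, ])
  }
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  inter <- function(s1, s2) {
    d1 <- cross(s2[1, ], s2[2, ], s1[1, ])
    d2 <- cross(s2[1, ], s2[2, ], s1[2, ])
    d3 <- cross(s1[1, ], s1[2, ], s2[1, ])
    d4 <- cross(s1[1, ], s1[2, ], s2[2, ])
    ((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))
  }
  if (n > 3) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ## skip adjacent edges (they share a vertex)
      if (abs(i - j) <= 1 || (i == 1 && j == n)) next
      if (inter(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

#' Rasterize a polygon onto the pixel grid of a calibrated image
#'
#' Pixel (i, j) (1-based row/col) covers the half-open square
#' \eqn{[(j-1)s, js) \times [(i-1)s, is)} with s = `um_per_px`; a pixel
#' belongs to the mask when its centre lies inside the polygon.
#'
#' @param poly two-column vertex matrix in micrometres.
#' @param nrow_px,ncol_px raster extent in pixels.
#' @param um_per_px calibration.
#' @return logical matrix.
#' @export
rasterize_poly <- function(poly, nrow_px, ncol_px, um_per_px) {
  cx <- (seq_len(ncol_px) - 0.5) * um_per_px
  cy <- (seq_len(nrow_px) - 0.5) * um_per_px
  g <- expand.grid(y = cy, x = cx)
  m <- points_in_poly(g$x, g$y, poly)
  matrix(m, nrow = nrow_px, ncol = ncol_px)
}

## Combined region mask: outline minus union of exclusion polygons.
region_mask <- function(outline, exclusions, nrow_px, ncol_px, um_per_px) {
  m <- rasterize_poly(outline, nrow_px, ncol_px, um_per_px)
  for (ex in exclusions %||% list())
    m <- m & !rasterize_poly(ex, nrow_px, ncol_px, um_per_px)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Pixel-centre coordinates (um) of TRUE entries / arbitrary indices.
px_centers <- function(idx, nrow_px, um_per_px) {
  i <- ((idx - 1L) %% nrow_px) + 1L
  j <- ((idx - 1L) %/% nrow_px) + 1L
  cbind(x = (j - 0.5) * um_per_px, y = (i - 0.5) * um_per_px)
}
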