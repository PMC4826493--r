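#' Construct a calibrated RGB image
#'
#' @param pixels H x W x 3 numeric array, values in \[0, 255\].
#' @param um_per_px physical calibration (micrometres per pixel), > 0.
#' @return object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, um_per_px) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("pixels must be an H x W x 3 array")
  if (!is.numeric(um_per_px) || length(um_per_px) != 1 || !is.finite(um_per_px) ||
      um_per_px <= 0)
    stop("um_per_px must be a positive number")
  structure(list(pixels = pixels, um_per_px = um_per_px),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px (%.3g x %.3g mm)\n",
              d[1], d[2], x$um_per_px,
              d[2] * x$um_per_px / 1000, d[1] * x$um_per_px / 1000))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' Write a calibrated image as PNG plus a calibration sidecar
#'
#' The calibration travels in `<path>.json` (`{"um_per_px": s}`) beside the
#' image, the precedence being: explicit config override, then sidecar.
#'
#' @param img `calibrated_image`.
#' @param path output `.png` path.
#' @export
write_image <- function(img, path) {
  arr <- pmin(pmax(img$pixels, 0), 255) / 255
  png::writePNG(arr, path)
  jsonlite::write_json(list(um_per_px = img$um_per_px),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated image (PNG + sidecar or explicit calibration)
#'
#' @param path PNG path.
#' @param um_per_px optional calibration override; if `NULL` the sidecar
#'   `<path>.json` must exist — there is no silent default.
#' @return `calibrated_image`.
#' @export
read_image <- function(path, um_per_px = NULL) {
  if (!file.exists(path)) stop("image not found: ", path)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE]
  if (is.null(um_per_px)) {
    sc <- paste0(path, ".json")
    if (!file.exists(sc))
      stop("no calibration: pass um_per_px or provide sidecar ", sc)
    um_per_px <- jsonlite::read_json(sc)$um_per_px
  }
  calibrated_image(arr * 255, um_per_px)
}

#' Read a polygon (with optional extra rings) from GeoJSON
#'
#' Coordinates are micrometres in the image frame (origin top-left, x
#' rightward, y downward).  A FeatureCollection yields a list of polygons;
#' a single Polygon yields one two-column matrix.
#'
#' @param path GeoJSON file.
#' @return two-column matrix, or list of such matrices.
#' @export
read_polygon <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  get_poly <- function(geom) {
    co <- geom$coordinates
    if (is.list(co)) co <- co[[1]]
    if (length(dim(co)) == 3) co <- co[1, , ]
    as_poly(co)
  }
  if (identical(g$type, "Polygon")) return(get_poly(g))
  if (identical(g$type, "Feature")) return(get_poly(g$geometry))
  if (identical(g$type, "FeatureCollection")) {
    geoms <- g$features$geometry
    if (is.data.frame(geoms)) {
      return(lapply(seq_len(nrow(geoms)), function(i)
        as_poly(geoms$coordinates[[i]][1, , ])))
    }
    return(lapply(geoms, get_poly))
  }
  stop("unsupported GeoJSON type: ", g$type)
}

#' Write one polygon as GeoJSON
#' @param poly two-column vertex matrix (um).
#' @param path output file.
#' @export
write_polygon <- function(poly, path) {
  p <- as_poly(poly)
  ring <- rbind(p, p[1, ])
  obj <- list(type = "Polygon",
              coordinates = list(lapply(seq_len(nrow(ring)), function(i)
                as.numeric(ring[i, ]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a detected cell set as CSV
#' @param cells `cell_set`.
#' @param path output file.
#' @export
write_cells <- function(cells, path) {
  write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}

#' Read a cell set from CSV
#' @param path CSV with at least columns `x_um`, `y_um`, `positive`.
#' @return `cell_set`.
#' @export
read_cells <- function(path) {
  df <- read.csv(path)
  if (!all(c("x_um", "y_um") %in% names(df)))
    stop("cell CSV needs x_um and y_um columns")
  if (is.null(df$positive)) df$positive <- TRUE
  as_cell_set(df)
}
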