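#' Color deconvolution into stain-density maps
#'
#' Converts RGB to optical density, \eqn{OD = -\log_{10}((I + \epsilon)/255)}
#' per channel, and projects each pixel onto the stain basis by the
#' inverse of the basis matrix.  Negative projections are clipped at 0.
#'
#' @param image a [calibrated_image()].
#' @param basis 3x3 stain basis (rows hematoxylin, dab, red); must be
#'   invertible.
#' @param od_eps small constant added to the intensity before the log.
#' @return named list of H x W density matrices: `hematoxylin`, `dab`,
#'   `red`.
#' @export
deconvolve <- function(image, basis = default_stain_basis(), od_eps = 1e-6) {
  if (kappa(basis, exact = TRUE) > 1e3)
    stop("stain basis is singular or ill-conditioned")
  px <- image$pixels
  nr <- dim(px)[1]; nc <- dim(px)[2]
  od <- -log10((pmax(px, 0) + od_eps) / 255)
  odm <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  dens <- odm %*% solve(basis)   # inverse of OD = dens %*% basis
  dens[dens < 0] <- 0
  list(hematoxylin = matrix(dens[, 1], nr, nc),
       dab = matrix(dens[, 2], nr, nc),
       red = matrix(dens[, 3], nr, nc))
}

#' Standard-deviation filter
#'
#' Each output pixel is the population standard deviation of the input in
#' a (2r+1) x (2r+1) window; edges are handled by symmetric reflection.
#' Enhances the contours of PHH3-positive nuclei in the DAB channel.
#'
#' @param map numeric matrix.
#' @param radius_px window radius in pixels, >= 1.
#' @return filtered matrix of the same shape.
#' @export
sd_filter <- function(map, radius_px = 2) {
  if (radius_px < 1) stop("radius_px must be >= 1")
  cpp_sd_filter(as.matrix(map), as.integer(radius_px))
}

#' HSI intensity band
#'
#' The intensity of the hue-saturation-intensity color model: the
#' arithmetic mean of R, G and B on the original 0-255 scale.  Dark pixels
#' (low intensity) highlight strong PHH3 positivity.
#'
#' @param image a [calibrated_image()].
#' @return H x W intensity matrix.
#' @export
hsi_intensity <- function(image) {
  (image$pixels[, , 1] + image$pixels[, , 2] + image$pixels[, , 3]) / 3
}

#' Classify pixels into the stain classes
#'
#' Deterministic rule cascade over deconvolved densities, the SD-filter
#' response of the DAB channel, and HSI intensity:
#' 1. `BACKGROUND` when intensity exceeds `bg_intensity` and every density
#'    is below `density_min`;
#' 2. else `PHH3` when the DAB density reaches `t_brown`, the pixel is
#'    more brown than blue (DAB density > hematoxylin density), and either
#'    the SD response reaches `t_sd` or the pixel is dark
#'    (intensity <= `t_dark`) — the darkness rescue keeps the interiors of
#'    dense metaphase bars that have low local variance;
#' 3. else `MART1` when the red density reaches `t_red`;
#' 4. else `HEMATOXYLIN` when the hematoxylin density reaches `t_blue`;
#' 5. else `BACKGROUND`.
#'
#' @param densities list from [deconvolve()].
#' @param sd_map SD-filter response of the DAB density map.
#' @param intensity_map HSI intensity map.
#' @param config an `ms_config` (its `$stains` thresholds are used).
#' @param um_per_px calibration carried into the result.
#' @return `class_map`: integer matrix with levels
#'   `BACKGROUND, PHH3, MART1, HEMATOXYLIN` (codes 0-3).
#' @export
classify_pixels <- function(densities, sd_map, intensity_map, config,
                            um_per_px) {
  th <- config$stains
  for (k in c("t_brown", "t_red", "t_blue", "t_sd", "t_dark",
              "bg_intensity", "density_min"))
    if (is.null(th[[k]])) stop("missing threshold key: stains$", k)
  dims <- dim(densities$dab)
  if (!identical(dims, dim(sd_map)) || !identical(dims, dim(intensity_map)))
    stop("density, sd and intensity maps must share one shape")
  bg <- intensity_map > th$bg_intensity &
    densities$hematoxylin < th$density_min &
    densities$dab < th$density_min & densities$red < th$density_min
  phh3 <- !bg & densities$dab >= th$t_brown &
    densities$dab > densities$hematoxylin &
    (sd_map >= th$t_sd | intensity_map <= th$t_dark)
  mart1 <- !bg & !phh3 & densities$red >= th$t_red
  hema <- !bg & !phh3 & !mart1 & densities$hematoxylin >= th$t_blue
  cm <- matrix(CL_BACKGROUND, dims[1], dims[2])
  cm[phh3] <- CL_PHH3
  cm[mart1] <- CL_MART1
  cm[hema] <- CL_HEMATOXYLIN
  structure(list(labels = cm, um_per_px = um_per_px,
                 levels = CLASS_LEVELS), class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, nbins = 4L)
  cat("<class_map>", nrow(x$labels), "x", ncol(x$labels), "px;",
      paste(sprintf("%s=%d", x$levels, tab), collapse = ", "), "\n")
  invisible(x)
}

#' Full pixel-classification stage
#'
#' Runs deconvolution, the SD filter on the DAB channel, HSI intensity and
#' the threshold cascade in one call.
#'
#' @param image a [calibrated_image()].
#' @param config an `ms_config`.
#' @return a `class_map`.
#' @export
classify_image <- function(image, config = default_config()) {
  dens <- deconvolve(image, config$stains$basis, config$stains$od_eps)
  sdm <- sd_filter(dens$dab, config$stains$sd_radius_px)
  inten <- hsi_intensity(image)
  classify_pixels(dens, sdm, inten, config, image$um_per_px)
}
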