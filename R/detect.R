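#' Fuse mitotic chromatin and label PHH3 objects
#'
#' Dilates the PHH3 pixel class by a disc of physical radius
#' `dilation_radius_um` so that the split chromatin of anaphase and
#' telophase figures merges into one connected component, then labels
#' components on the dilated mask.  All subsequent measurements (area,
#' centroid, mean density) are taken on the original, undilated member
#' pixels.
#'
#' @param class_map a `class_map`.
#' @param dilation_radius_um disc radius in micrometres, >= 0.
#' @return list with `labels` (integer matrix over the original PHH3
#'   pixels; 0 = background), `n` objects, and `um_per_px`.
#' @export
fuse_chromatin <- function(class_map, dilation_radius_um = 2.5) {
  if (dilation_radius_um < 0) stop("dilation_radius_um must be >= 0")
  s <- class_map$um_per_px
  mask <- class_map$labels == CL_PHH3
  r_px <- dilation_radius_um / s
  dil <- if (r_px > 0) cpp_dilate_disc(mask, r_px) else mask
  lab <- cpp_label(dil)
  lab[!mask] <- 0L
  ## relabel 1..n in first-appearance order
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) && !identical(ids, seq_along(ids)))
    lab[lab > 0L] <- match(lab[lab > 0L], ids)
  list(labels = lab, n = length(ids), um_per_px = s)
}

## Bounding box (row/col ranges) of a set of linear indices, padded.
bbox_of <- function(idx, nr, nc, pad = 0L) {
  i <- ((idx - 1L) %% nr) + 1L
  j <- ((idx - 1L) %/% nr) + 1L
  list(i0 = max(1L, min(i) - pad), i1 = min(nr, max(i) + pad),
       j0 = max(1L, min(j) - pad), j1 = min(nc, max(j) + pad),
       i = i, j = j)
}

#' MART1 surround fraction of an object
#'
#' Fraction of a perinuclear ring classified MART1.  The ring is the
#' dilation of the object's pixels by `ring_width_um` minus the object
#' itself; at image borders the fraction is taken over the available ring
#' pixels.
#'
#' @param idx linear pixel indices of the object.
#' @param class_map a `class_map`.
#' @param ring_width_um ring width in micrometres, > 0.
#' @return fraction in \[0, 1\].
#' @export
mart1_surround <- function(idx, class_map, ring_width_um = 2) {
  if (ring_width_um <= 0) stop("ring_width_um must be > 0")
  s <- class_map$um_per_px
  labs <- class_map$labels
  nr <- nrow(labs); nc <- ncol(labs)
  pad <- as.integer(ceiling(ring_width_um / s)) + 1L
  bb <- bbox_of(idx, nr, nc, pad)
  sub <- matrix(FALSE, bb$i1 - bb$i0 + 1L, bb$j1 - bb$j0 + 1L)
  sub[cbind(bb$i - bb$i0 + 1L, bb$j - bb$j0 + 1L)] <- TRUE
  ring <- cpp_dilate_disc(sub, ring_width_um / s) & !sub
  if (!any(ring)) return(0)
  cls <- labs[bb$i0:bb$i1, bb$j0:bb$j1, drop = FALSE]
  sum(cls[ring] == CL_MART1) / sum(ring)
}

## 1 - solidity of a pixel set; solidity = pixel count / pixels inside the
## convex hull of the member pixel centres (grid-filled, clamped to <= 1).
irregularity_of <- function(idx, nr, nc, s) {
  bb <- bbox_of(idx, nr, nc)
  x <- (bb$j - 0.5) * s
  y <- (bb$i - 0.5) * s
  n <- length(idx)
  if (n < 3) return(0)
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(0)
  h <- chull(pts)
  if (length(h) < 3) return(0)
  hull <- pts[h, , drop = FALSE]
  ## tiny outward scaling keeps boundary pixel centres inside the hull
  ctr <- colMeans(hull)
  hull <- sweep(sweep(hull, 2, ctr) * (1 + 1e-9), 2, ctr, "+")
  gx <- (bb$j0:bb$j1 - 0.5) * s
  gy <- (bb$i0:bb$i1 - 0.5) * s
  g <- expand.grid(y = gy, x = gx)
  eps <- s * 1e-6
  n_hull <- sum(points_in_poly(g$x, g$y, hull) |
                points_in_poly(g$x + eps, g$y + eps, hull))
  sol <- min(1, n / max(n_hull, n))
  1 - sol
}

#' Measure PHH3 object features
#'
#' @param fused result of [fuse_chromatin()].
#' @param class_map the `class_map` the objects came from.
#' @param dab_density DAB density matrix from [deconvolve()].
#' @param config an `ms_config`.
#' @return data.frame of per-object features: `x_um`, `y_um`, `area_um2`,
#'   `mean_brown_od`, `irregularity`, `mart1_surround_fraction`.
#' @export
object_features <- function(fused, class_map, dab_density, config) {
  s <- fused$um_per_px
  labs <- fused$labels
  nr <- nrow(labs); nc <- ncol(labs)
  idx_by <- split(which(labs > 0L), labs[labs > 0L])
  feat <- lapply(idx_by, function(idx) {
    ctr <- px_centers(idx, nr, s)
    data.frame(
      x_um = mean(ctr[, 1]), y_um = mean(ctr[, 2]),
      area_um2 = length(idx) * s^2,
      mean_brown_od = mean(dab_density[idx]),
      irregularity = irregularity_of(idx, nr, nc, s),
      mart1_surround_fraction =
        mart1_surround(idx, class_map, config$detect$ring_width_um))
  })
  if (!length(feat))
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), mean_brown_od = numeric(0),
                      irregularity = numeric(0),
                      mart1_surround_fraction = numeric(0)))
  do.call(rbind, feat)
}

#' Score objects into PHH3/MART1-positive cells
#'
#' An object is positive iff its area lies within
#' `[min_area_um2, max_area_um2]`, its mean DAB optical density reaches
#' `od_min`, its MART1 surround fraction reaches `surround_min`, and its
#' irregularity (1 - solidity) does not exceed `irregularity_max`.  Every
#' object is retained with its features and flag for auditability.
#'
#' @param features data.frame from [object_features()].
#' @param config an `ms_config`.
#' @param um_per_px calibration recorded on the result.
#' @return a `cell_set` (data.frame with a `positive` column plus
#'   provenance attributes).
#' @export
score_objects <- function(features, config, um_per_px = NA_real_) {
  d <- config$detect
  features$positive <-
    features$area_um2 >= d$min_area_um2 &
    features$area_um2 <= d$max_area_um2 &
    features$mean_brown_od >= d$od_min &
    features$mart1_surround_fraction >= d$surround_min &
    features$irregularity <= d$irregularity_max
  as_cell_set(features, um_per_px = um_per_px,
              config_hash = config_hash(config))
}

#' @rdname score_objects
#' @param df data.frame with at least `x_um`, `y_um`, `positive`.
#' @export
as_cell_set <- function(df, um_per_px = NA_real_, config_hash = NA_character_) {
  structure(df, class = c("cell_set", "data.frame"),
            um_per_px = um_per_px, config_hash = config_hash)
}

#' @export
print.cell_set <- function(x, ...) {
  cat(sprintf("<cell_set> %d objects, %d positive\n", nrow(x), sum(x$positive)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Positive centroids of a cell set
#' @param cells a `cell_set`.
#' @return n x 2 matrix (x_um, y_um) of positive cells.
#' @export
positive_centroids <- function(cells) {
  p <- cells[cells$positive, , drop = FALSE]
  cbind(x = p$x_um, y = p$y_um)
}

#' MART1-verified tumor area
#'
#' Within the outline (minus exclusions), the reference space is the union
#' of MART1 pixels, hematoxylin-nucleus components whose MART1 surround
#' reaches `surround_min` (PHH3-negative tumor nuclei reclassified into
#' MART1), and the pixels of positive PHH3 cells.  Holes up to
#' `hole_max_um2` are filled.
#'
#' @param class_map a `class_map`.
#' @param outline tumor outline polygon (um), or `NULL` for whole frame.
#' @param exclusions list of exclusion polygons.
#' @param config an `ms_config`.
#' @param positive_labels optional integer matrix from [fuse_chromatin()]
#'   with a `cell_set` in `cells`: pixels of positive cells join the mask.
#' @param cells optional `cell_set` matching `positive_labels`.
#' @return `tumor_mask`: list with logical `mask`, `area_mm2`, `um_per_px`.
#' @export
tumor_area <- function(class_map, outline = NULL, exclusions = NULL,
                       config = default_config(),
                       positive_labels = NULL, cells = NULL) {
  labs <- class_map$labels
  s <- class_map$um_per_px
  nr <- nrow(labs); nc <- ncol(labs)
  region <- if (is.null(outline)) matrix(TRUE, nr, nc)
            else region_mask(outline, exclusions, nr, nc, s)
  mask <- (labs == CL_MART1) & region
  ## reclassify PHH3-negative tumor nuclei (blue with MART1 surrounding)
  blue <- (labs == CL_HEMATOXYLIN) & region
  if (any(blue)) {
    bl <- cpp_label(blue)
    for (idx in split(which(bl > 0L), bl[bl > 0L])) {
      fr <- mart1_surround(idx, class_map, config$detect$ring_width_um)
      if (fr >= config$detect$surround_min) mask[idx] <- TRUE
    }
  }
  ## positive PHH3 cells belong to the tumor area
  if (!is.null(positive_labels) && !is.null(cells) && nrow(cells)) {
    pos_ids <- which(cells$positive)
    mask[positive_labels %in% pos_ids & region] <- TRUE
  }
  mask <- fill_holes(mask, max_px = config$detect$hole_max_um2 / s^2)
  mask <- mask & region
  structure(list(mask = mask, area_mm2 = sum(mask) * s^2 / 1e6,
                 um_per_px = s), class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("<tumor_mask> %.4g mm^2 (%d px)\n", x$area_mm2, sum(x$mask)))
  invisible(x)
}

## Fill background components of bounded size not touching the border.
fill_holes <- function(mask, max_px) {
  if (max_px <= 0) return(mask)
  comp <- cpp_label(!mask)
  nr <- nrow(mask); nc <- ncol(mask)
  border <- unique(c(comp[1, ], comp[nr, ], comp[, 1], comp[, nc]))
  tab <- tabulate(comp)
  for (id in seq_along(tab)) {
    if (tab[id] == 0 || id %in% border) next
    if (tab[id] <= max_px) mask[comp == id] <- TRUE
  }
  mask
}

#' Detect PHH3/MART1-positive cells and the tumor area in one pass
#'
#' The full chain: pixel classification, restriction to the outline minus
#' exclusions, chromatin fusion, per-object features, positivity scoring,
#' and the MART1-verified tumor area.  Deterministic for a fixed config.
#'
#' @param image a [calibrated_image()].
#' @param outline tumor outline polygon (um); `NULL` analyses the frame.
#' @param exclusions list of exclusion polygons (epidermis, adnexa).
#' @param config an `ms_config`.
#' @return list with `cells` (`cell_set`), `tumor` (`tumor_mask`),
#'   `class_map`, and `stats` (per-stage pixel/object counts for audit).
#' @export
detect_cells <- function(image, outline = NULL, exclusions = NULL,
                         config = default_config()) {
  if (is.null(image$um_per_px) || !is.finite(image$um_per_px))
    stop("image calibration unknown")
  dens <- deconvolve(image, config$stains$basis, config$stains$od_eps)
  sdm <- sd_filter(dens$dab, config$stains$sd_radius_px)
  inten <- hsi_intensity(image)
  cm <- classify_pixels(dens, sdm, inten, config, image$um_per_px)
  nr <- nrow(cm$labels); nc <- ncol(cm$labels)
  if (!is.null(outline)) {
    region <- region_mask(outline, exclusions, nr, nc, image$um_per_px)
    cm$labels[!region] <- CL_BACKGROUND
  }
  class_px <- tabulate(cm$labels + 1L, nbins = 4L)
  fused <- fuse_chromatin(cm, config$detect$dilation_radius_um)
  feats <- object_features(fused, cm, dens$dab, config)
  cells <- score_objects(feats, config, um_per_px = image$um_per_px)
  tumor <- tumor_area(cm, outline, exclusions, config,
                      positive_labels = fused$labels, cells = cells)
  stats <- list(pixels_per_class = stats::setNames(class_px, CLASS_LEVELS),
                objects_total = nrow(cells),
                objects_positive = sum(cells$positive))
  list(cells = cells, tumor = tumor, class_map = cm, stats = stats)
}

#' Greedy one-to-one centroid matching for evaluation
#'
#' Matches detected positives to ground-truth centroids by increasing
#' distance, one-to-one, within a nucleus-scale tolerance.
#'
#' @param detected n x 2 matrix (x, y) of detected positive centroids.
#' @param truth m x 2 matrix of true centroids.
#' @param tol_um maximum match distance.
#' @return list with `tp`, `fp`, `fn`, `sensitivity`, `precision`.
#' @export
match_centroids <- function(detected, truth, tol_um = 5) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    tp <- 0L
  } else {
    d2 <- outer(detected[, 1], truth[, 1], "-")^2 +
          outer(detected[, 2], truth[, 2], "-")^2
    d2[d2 > tol_um^2] <- Inf
    tp <- 0L
    while (any(is.finite(d2))) {
      k <- arrayInd(which.min(d2), dim(d2))
      tp <- tp + 1L
      d2[k[1], ] <- Inf
      d2[, k[2]] <- Inf
    }
  }
  list(tp = tp, fp = nd - tp, fn = nt - tp,
       sensitivity = if (nt > 0) tp / nt else NA_real_,
       precision = if (nd > 0) tp / nd else NA_real_)
}
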