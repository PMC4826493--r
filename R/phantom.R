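#' Specify a synthetic dual-stain slide phantom
#'
#' The phantom emulates a PHH3/MART1 dual-stained melanoma section: a
#' lesion filled with red (AP-red) MART1 cytoplasm, blue (hematoxylin)
#' PHH3-negative tumor nuclei, brown (DAB) PHH3-positive mitotic figures
#' whose morphology follows the mitotic phase (prophase disc, metaphase
#' bar, anaphase/telophase chromatin split into two blobs), plus the
#' classic confounders of automated reading: PHH3-positive lymphocytes in
#' the peritumoral stroma (no MART1 surrounding), speckled brown pigment
#' clumps inside the lesion, pale-MART1 patches and over-dark MART1
#' patches.  A configurable fraction of the positives is planted as an
#' isotropic Gaussian cluster to create a known hot spot.
#'
#' @param width_um,height_um physical extent of the image (micrometres).
#' @param um_per_px calibration; default 0.46 um/px (a typical 20X scan).
#' @param lesion_polygon tumor outline, two-column (x, y) matrix in um.
#' @param n_tumor_nuclei PHH3-negative tumor nuclei.
#' @param n_positive PHH3+/MART1+ cells.
#' @param cluster_center,cluster_sd_um,cluster_fraction planted hot-spot
#'   parameters: `cluster_fraction` of the positives are drawn from an
#'   isotropic Gaussian of this standard deviation around the center.
#' @param n_lymphocytes PHH3+ cells without MART1 surrounding (stromal).
#' @param n_pigment brown pigment granule clumps inside the lesion.
#' @param pale_mart1_fraction fraction of the lesion rendered with a red
#'   stain amount too weak to classify as MART1.
#' @param dark_mart1_fraction fraction rendered with over-dark red.
#' @param phase_mix proportions of prophase/metaphase/anaphase/telophase
#'   mitotic morphologies; must sum to 1.
#' @param chromatin_gap_um edge-to-edge gap between the two chromatin
#'   blobs of anaphase/telophase figures.
#' @param noise_sd additive Gaussian pixel noise (8-bit units).
#' @param min_dist_um minimum centre-to-centre distance between nuclei.
#' @param positive_min_dist_um minimum distance between distinct positive
#'   cells (mitotic figures are sparse in tissue; this also keeps distinct
#'   figures resolvable by the chromatin-fusion dilation).
#' @param seed RNG seed; identical spec + seed gives a bit-identical
#'   phantom.
#' @return validated `phantom_spec` list.
#' @export
phantom_spec <- function(width_um = 1500, height_um = 1500, um_per_px = 0.46,
                         lesion_polygon = NULL,
                         n_tumor_nuclei = 300, n_positive = 50,
                         cluster_center = NULL, cluster_sd_um = 150,
                         cluster_fraction = 0.8,
                         n_lymphocytes = 8, n_pigment = 12,
                         pale_mart1_fraction = 0.05,
                         dark_mart1_fraction = 0.03,
                         phase_mix = c(prophase = 0.3, metaphase = 0.3,
                                       anaphase = 0.2, telophase = 0.2),
                         chromatin_gap_um = 4, noise_sd = 3,
                         min_dist_um = 8, positive_min_dist_um = 30,
                         seed = 1L) {
  if (width_um <= 0 || height_um <= 0) stop("phantom dimensions must be positive")
  if (um_per_px <= 0) stop("um_per_px must be positive")
  if (is.null(lesion_polygon)) {
    ## default lesion: irregular octagon centred in the field
    cx <- width_um / 2; cy <- height_um / 2
    r <- 0.38 * min(width_um, height_um) *
      c(1.00, 0.85, 0.95, 0.80, 1.00, 0.90, 0.85, 0.95)
    th <- (0:7) * pi / 4
    lesion_polygon <- cbind(cx + r * cos(th), cy + r * sin(th))
  }
  lesion_polygon <- as_poly(lesion_polygon)
  if (!poly_is_simple(lesion_polygon)) stop("lesion_polygon must be simple")
  if (is.null(cluster_center))
    cluster_center <- colMeans(lesion_polygon)
  counts <- c(n_tumor_nuclei, n_positive, n_lymphocytes, n_pigment)
  if (any(counts < 0)) stop("counts must be >= 0")
  fr <- c(cluster_fraction, pale_mart1_fraction, dark_mart1_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (abs(sum(phase_mix) - 1) > 1e-6) stop("phase_mix must sum to 1")
  if (length(phase_mix) != 4) stop("phase_mix needs 4 proportions")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  spec <- list(width_um = width_um, height_um = height_um,
               um_per_px = um_per_px, lesion_polygon = lesion_polygon,
               n_tumor_nuclei = as.integer(n_tumor_nuclei),
               n_positive = as.integer(n_positive),
               cluster_center = as.numeric(cluster_center),
               cluster_sd_um = cluster_sd_um,
               cluster_fraction = cluster_fraction,
               n_lymphocytes = as.integer(n_lymphocytes),
               n_pigment = as.integer(n_pigment),
               pale_mart1_fraction = pale_mart1_fraction,
               dark_mart1_fraction = dark_mart1_fraction,
               phase_mix = phase_mix, chromatin_gap_um = chromatin_gap_um,
               noise_sd = noise_sd, min_dist_um = min_dist_um,
               positive_min_dist_um = positive_min_dist_um,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

## Rejection sampling of points with a minimum pairwise distance.
## `propose()` returns one candidate c(x, y); `ok(x, y)` tests region
## membership.  Errors out after bounded attempts (density infeasible).
sample_min_dist <- function(n, propose, ok, min_dist, existing = NULL,
                            max_attempts = 400L * max(n, 1L)) {
  pts <- matrix(numeric(0), ncol = 2)
  avoid <- if (is.null(existing)) matrix(numeric(0), ncol = 2) else existing
  attempts <- 0L
  while (nrow(pts) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("sampling failed: requested density infeasible after ",
           max_attempts, " attempts")
    p <- propose()
    if (!ok(p[1], p[2])) next
    all_pts <- rbind(pts, avoid)
    if (min_dist > 0 && nrow(all_pts) > 0) {
      d2 <- (all_pts[, 1] - p[1])^2 + (all_pts[, 2] - p[2])^2
      if (any(d2 < min_dist^2)) next
    }
    pts <- rbind(pts, p)
  }
  unname(pts)
}

#' Sample PHH3-positive cell positions for a phantom
#'
#' `cluster_fraction` of the `n_positive` centroids are drawn from an
#' isotropic Gaussian around `cluster_center` (rejection-sampled into the
#' lesion); the remainder are uniform over the lesion.  Positions keep a
#' minimum pairwise distance and an inset from the lesion boundary so that
#' a whole cell (cytoplasm and perinuclear ring) fits inside the outline.
#'
#' @param spec a `phantom_spec`.
#' @param min_dist_um minimum centre-to-centre distance; default the
#'   spec's `positive_min_dist_um`; use 0 to disable.
#' @param inset_um minimum distance from the lesion boundary.
#' @return n x 2 matrix of (x, y) centroids in micrometres.
#' @export
sample_positions <- function(spec, min_dist_um = NULL, inset_um = 12) {
  if (poly_area(spec$lesion_polygon) <= 0) stop("lesion area must be positive")
  if (is.null(min_dist_um)) min_dist_um <- spec$positive_min_dist_um
  n <- spec$n_positive
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  n_cl <- round(spec$cluster_fraction * n)
  bb <- apply(spec$lesion_polygon, 2, range)
  ok <- function(x, y) {
    points_in_poly(x, y, spec$lesion_polygon) &&
      (inset_um <= 0 || dist_to_poly_edge(x, y, spec$lesion_polygon) >= inset_um)
  }
  cl <- sample_min_dist(n_cl, function()
    spec$cluster_center + rnorm(2, sd = spec$cluster_sd_um), ok, min_dist_um)
  bg <- sample_min_dist(n - n_cl, function()
    c(runif(1, bb[1, 1], bb[2, 1]), runif(1, bb[1, 2], bb[2, 2])),
    ok, min_dist_um, existing = cl)
  pts <- rbind(cl, bg)
  colnames(pts) <- c("x", "y")
  pts
}

## --- painting primitives -------------------------------------------------

## Add `amount` to `mat` wherever test(dx, dy) is TRUE within a bounding
## box of `extent` um around (cx, cy).  `mode = "set"` overwrites.
paint_shape <- function(mat, s, cx, cy, extent, test, amount, mode = "add") {
  nr <- nrow(mat); nc <- ncol(mat)
  j0 <- max(1L, floor((cx - extent) / s) + 1L)
  j1 <- min(nc, ceiling((cx + extent) / s))
  i0 <- max(1L, floor((cy - extent) / s) + 1L)
  i1 <- min(nr, ceiling((cy + extent) / s))
  if (j0 > j1 || i0 > i1) return(mat)
  jj <- j0:j1; ii <- i0:i1
  dx <- outer(rep(1, length(ii)), (jj - 0.5) * s - cx)
  dy <- outer((ii - 0.5) * s - cy, rep(1, length(jj)))
  sel <- test(dx, dy)
  sub <- mat[ii, jj, drop = FALSE]
  if (mode == "add") sub[sel] <- sub[sel] + amount else sub[sel] <- amount
  mat[ii, jj] <- sub
  mat
}

ellipse_test <- function(a, b, theta) {
  ct <- cos(theta); st <- sin(theta)
  function(dx, dy) ((dx * ct + dy * st) / a)^2 + ((-dx * st + dy * ct) / b)^2 <= 1
}

bar_test <- function(len, wid, theta) {
  ct <- cos(theta); st <- sin(theta)
  function(dx, dy) abs(dx * ct + dy * st) <= len / 2 &
    abs(-dx * st + dy * ct) <= wid / 2
}

## Paint one mitotic figure; returns the updated DAB amount matrix.
paint_figure <- function(A_d, s, x, y, phase, gap, amount) {
  if (phase == "prophase") {
    r <- runif(1, 3.2, 4.0)
    A_d <- paint_shape(A_d, s, x, y, r + s, ellipse_test(r, r, 0), amount)
  } else if (phase == "metaphase") {
    th <- runif(1, 0, pi)
    A_d <- paint_shape(A_d, s, x, y, 5 + s, bar_test(8, 2.5, th), amount)
  } else {
    r <- if (phase == "anaphase") 2.5 else 2.2
    th <- runif(1, 0, pi)
    d <- (gap + 2 * r) / 2
    for (sgn in c(-1, 1)) {
      bx <- x + sgn * d * cos(th); by <- y + sgn * d * sin(th)
      A_d <- paint_shape(A_d, s, bx, by, r + s, ellipse_test(r, r, 0), amount)
    }
  }
  A_d
}

## Stain amounts used by the forward Beer-Lambert renderer.
## red_dark stays below 8-bit saturation: a fully saturated patch would
## destroy the OD information that lets deconvolution separate dark MART1
## from PHH3 (intensity ~ 55, inside the darkness band of the classifier).
PHANTOM_AMOUNTS <- list(
  red_cytoplasm = 0.7, red_pale = 0.08, red_dark = 1.6,
  hematoxylin_nucleus = 0.9, dab_figure = 1.1, dab_lymphocyte = 1.0,
  dab_pigment = 1.3)

#' Render a phantom slide image with ground truth
#'
#' Per-pixel stain amounts are composed shape by shape and converted to
#' RGB through the forward Beer-Lambert model
#' \eqn{I = 255 \cdot 10^{-\sum_k a_k v_k}} with the package's stain basis,
#' so that color deconvolution is an approximate inverse.  Deterministic
#' for a fixed spec and seed.
#'
#' @param spec a `phantom_spec`.
#' @param basis stain basis used for rendering; default
#'   [default_stain_basis()].
#' @return list with `image` (a [calibrated_image()]) and `truth`, a
#'   `ground_truth` list: `positive_centroids` (x_um, y_um, phase),
#'   `confounder_centroids` (x_um, y_um, kind), `tumor_mask` (logical
#'   matrix: the true MART1 tumor area), `planted_cluster_center`,
#'   `lesion_polygon`, `um_per_px`.
#' @export
render_phantom <- function(spec, basis = default_stain_basis()) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$um_per_px
  nc <- max(1L, round(spec$width_um / s))
  nr <- max(1L, round(spec$height_um / s))
  am <- PHANTOM_AMOUNTS
  with_seed(spec$seed, {
    pos <- sample_positions(spec)
    phases <- if (spec$n_positive > 0)
      sample(names(spec$phase_mix), spec$n_positive, TRUE, spec$phase_mix)
    else character(0)

    in_lesion <- function(x, y) points_in_poly(x, y, spec$lesion_polygon)
    bb <- apply(spec$lesion_polygon, 2, range)
    unif_lesion <- function() c(runif(1, bb[1, 1], bb[2, 1]),
                                runif(1, bb[1, 2], bb[2, 2]))
    ## PHH3-negative tumor nuclei: min_dist apart, clear of mitotic figures
    nuc <- sample_min_dist(spec$n_tumor_nuclei, unif_lesion, in_lesion,
                           spec$min_dist_um,
                           existing = if (nrow(pos)) pos else NULL)
    if (nrow(pos) && nrow(nuc)) {
      keep <- vapply(seq_len(nrow(nuc)), function(i)
        min((pos[, 1] - nuc[i, 1])^2 + (pos[, 2] - nuc[i, 2])^2) >= 12^2,
        logical(1))
      nuc <- nuc[keep, , drop = FALSE]
    }
    ## lymphocytes: peritumoral stroma (outside the lesion, clear of it)
    lym <- sample_min_dist(spec$n_lymphocytes, function()
      c(runif(1, 8, spec$width_um - 8), runif(1, 8, spec$height_um - 8)),
      function(x, y) !in_lesion(x, y) &&
        dist_to_poly_edge(x, y, spec$lesion_polygon) >= 8,
      spec$min_dist_um)
    ## pigment clumps: well inside the lesion (no outline clipping of the
    ## aggregate), clear of positives so they cannot fuse with chromatin
    pig_ok <- function(x, y) in_lesion(x, y) &&
      dist_to_poly_edge(x, y, spec$lesion_polygon) >= 15 &&
      (nrow(pos) == 0 ||
       min((pos[, 1] - x)^2 + (pos[, 2] - y)^2) >= 30^2)
    pig <- sample_min_dist(spec$n_pigment, unif_lesion, pig_ok,
                           max(spec$min_dist_um, 28))

    A_h <- matrix(0, nr, nc); A_d <- matrix(0, nr, nc); A_r <- matrix(0, nr, nc)
    lesion_mask <- rasterize_poly(spec$lesion_polygon, nr, nc, s)
    A_r[lesion_mask] <- am$red_cytoplasm
    ## pale / over-dark MART1 patches (disc-shaped staining artifacts)
    patch_r <- 40
    lesion_area <- poly_area(spec$lesion_polygon)
    for (mode in c("pale", "dark")) {
      frac <- if (mode == "pale") spec$pale_mart1_fraction else spec$dark_mart1_fraction
      npatch <- round(frac * lesion_area / (pi * patch_r^2))
      amt <- if (mode == "pale") am$red_pale else am$red_dark
      if (npatch > 0) {
        patch <- matrix(0, nr, nc)
        k <- 0L
        while (k < npatch) {
          p <- unif_lesion()
          if (!in_lesion(p[1], p[2])) next
          patch <- paint_shape(patch, s, p[1], p[2], patch_r + s,
                               ellipse_test(patch_r, patch_r, 0), 1, mode = "set")
          k <- k + 1L
        }
        A_r[patch > 0 & lesion_mask] <- amt
      }
    }
    ## tumor nuclei: blue ellipses; cytoplasmic MART1 does not stain the
    ## nucleus, so red is cleared underneath (these pixels classify as
    ## hematoxylin and must be reclassified into the tumor area later)
    if (nrow(nuc)) for (i in seq_len(nrow(nuc))) {
      a <- runif(1, 3.5, 5); b <- a * runif(1, 0.55, 0.85); th <- runif(1, 0, pi)
      test <- ellipse_test(a, b, th)
      A_r <- paint_shape(A_r, s, nuc[i, 1], nuc[i, 2], a + s, test, 0,
                         mode = "set")
      A_h <- paint_shape(A_h, s, nuc[i, 1], nuc[i, 2], a + s, test,
                         am$hematoxylin_nucleus)
    }
    ## mitotic figures (brown)
    if (nrow(pos)) for (i in seq_len(nrow(pos)))
      A_d <- paint_figure(A_d, s, pos[i, 1], pos[i, 2], phases[i],
                          spec$chromatin_gap_um, am$dab_figure)
    ## lymphocytes (brown discs, no MART1 around)
    if (nrow(lym)) for (i in seq_len(nrow(lym)))
      A_d <- paint_shape(A_d, s, lym[i, 1], lym[i, 2], 3 + s,
                         ellipse_test(3, 3, 0), am$dab_lymphocyte)
    ## pigment: melanophage-like aggregates of coarse granules.  The
    ## granules overlap around a ring, so the fused object's area always
    ## exceeds the nucleus size gate (> max_area), while stray satellite
    ## granules stay below the minimum size — the size/irregularity gates
    ## are the designed defense against this confounder.
    if (nrow(pig)) for (i in seq_len(nrow(pig))) {
      k <- 18L
      ring_r <- runif(1, 7.0, 8.0)
      th <- runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
      for (q in seq_len(k)) {
        gr <- runif(1, 1.8, 2.1)
        rr <- ring_r + runif(1, -0.3, 0.3)
        A_d <- paint_shape(A_d, s, pig[i, 1] + rr * cos(th[q]),
                           pig[i, 2] + rr * sin(th[q]), gr + s,
                           ellipse_test(gr, gr, 0), am$dab_pigment)
      }
      for (q in seq_len(sample(2:3, 1))) {
        ang <- runif(1, 0, 2 * pi); rad <- runif(1, 11, 13)
        gr <- runif(1, 0.5, 0.7)
        A_d <- paint_shape(A_d, s, pig[i, 1] + rad * cos(ang),
                           pig[i, 2] + rad * sin(ang), gr + s,
                           ellipse_test(gr, gr, 0), am$dab_pigment)
      }
    }

    img <- forward_beer_lambert(A_h, A_d, A_r, basis)
    if (spec$noise_sd > 0)
      img <- img + array(rnorm(length(img), sd = spec$noise_sd), dim(img))
    img <- round(pmin(pmax(img, 0), 255))

    conf <- rbind(
      if (nrow(lym)) data.frame(x_um = lym[, 1], y_um = lym[, 2],
                                kind = "lymphocyte"),
      if (nrow(pig)) data.frame(x_um = pig[, 1], y_um = pig[, 2],
                                kind = "pigment"))
    if (is.null(conf))
      conf <- data.frame(x_um = numeric(0), y_um = numeric(0),
                         kind = character(0))
    truth <- structure(list(
      positive_centroids = data.frame(
        x_um = if (nrow(pos)) pos[, 1] else numeric(0),
        y_um = if (nrow(pos)) pos[, 2] else numeric(0),
        phase = phases),
      confounder_centroids = conf,
      tumor_mask = lesion_mask,
      planted_cluster_center = spec$cluster_center,
      lesion_polygon = spec$lesion_polygon,
      um_per_px = s), class = "ground_truth")
    list(image = calibrated_image(img, s), truth = truth)
  })
}

#' Forward Beer-Lambert renderer
#'
#' @param A_h,A_d,A_r per-pixel stain amount matrices (hematoxylin, DAB,
#'   AP-red).
#' @param basis stain basis (rows = stains, columns = R, G, B).
#' @return H x W x 3 numeric array on the 0-255 scale (not rounded).
#' @export
forward_beer_lambert <- function(A_h, A_d, A_r, basis = default_stain_basis()) {
  nr <- nrow(A_h); nc <- ncol(A_h)
  img <- array(0, c(nr, nc, 3))
  for (ch in 1:3) {
    od <- A_h * basis[1, ch] + A_d * basis[2, ch] + A_r * basis[3, ch]
    img[, , ch] <- 255 * 10^(-od)
  }
  img
}

#' Write phantom artifacts to a directory
#'
#' Image as PNG with calibration sidecar, ground-truth centroids as CSV
#' (x_um, y_um, kind), tumor mask as PNG, lesion outline as GeoJSON.
#'
#' @param phantom result of [render_phantom()].
#' @param dir output directory (created if needed).
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(phantom$image, file.path(dir, "phantom.png"))
  tr <- phantom$truth
  cent <- rbind(
    if (nrow(tr$positive_centroids))
      data.frame(x_um = tr$positive_centroids$x_um,
                 y_um = tr$positive_centroids$y_um, kind = "positive"),
    tr$confounder_centroids)
  if (is.null(cent))
    cent <- data.frame(x_um = numeric(0), y_um = numeric(0), kind = character(0))
  write.csv(cent, file.path(dir, "truth_centroids.csv"), row.names = FALSE)
  png::writePNG(tr$tumor_mask * 1, file.path(dir, "tumor_mask.png"))
  write_polygon(tr$lesion_polygon, file.path(dir, "lesion.geojson"))
  invisible(dir)
}
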