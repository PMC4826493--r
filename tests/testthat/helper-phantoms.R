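# Shared phantom presets.  Coarse calibration (2 um/px) keeps renders fast;
# tests that depend on the fusion dilation resolving 4-um chromatin gaps
# use 1 um/px.

small_spec <- function(seed = 1, width_um = 800, height_um = 800,
                       um_per_px = 2, n_tumor_nuclei = 80, n_positive = 15,
                       cluster_sd_um = 80, n_lymphocytes = 3, n_pigment = 4,
                       ...) {
  phantom_spec(width_um = width_um, height_um = height_um,
               um_per_px = um_per_px, n_tumor_nuclei = n_tumor_nuclei,
               n_positive = n_positive, cluster_sd_um = cluster_sd_um,
               n_lymphocytes = n_lymphocytes, n_pigment = n_pigment,
               seed = seed, ...)
}

# no confounders, no noise
clean_spec <- function(seed = 1, ...) {
  small_spec(seed = seed, n_lymphocytes = 0, n_pigment = 0,
             pale_mart1_fraction = 0, dark_mart1_fraction = 0,
             noise_sd = 0, ...)
}

default_spec <- function(seed = 1, ...) {
  phantom_spec(um_per_px = 2, seed = seed, ...)
}

# Brute-force within-radius counts over a fixed grid (heat-map oracle).
oracle_circle_counts <- function(cen, xs, ys, radius) {
  ny <- length(ys); nx <- length(xs)
  out <- matrix(0L, ny, nx)
  if (nrow(cen) == 0) return(out)
  for (j in seq_len(nx)) {
    dx2 <- (cen[, 1] - xs[j])^2
    for (i in seq_len(ny))
      out[i, j] <- sum(dx2 + (cen[, 2] - ys[i])^2 <= radius^2)
  }
  out
}

# Brute-force best 1-mm^2 square placement over candidate centres on a
# grid: returns the maximum half-open-square count.
oracle_square_max <- function(cen, xs, ys, side = 1000) {
  half <- side / 2
  best <- 0L
  for (gx in xs) {
    inx <- cen[, 1] >= gx - half & cen[, 1] < gx + half
    if (!any(inx)) next
    ysub <- cen[inx, 2]
    for (gy in ys) {
      cnt <- sum(ysub >= gy - half & ysub < gy + half)
      if (cnt > best) best <- cnt
    }
  }
  best
}
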