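test_that("empty phantom renders pure background with empty truth", {
  spec <- phantom_spec(width_um = 200, height_um = 200, um_per_px = 2,
                       n_tumor_nuclei = 0, n_positive = 0, n_lymphocytes = 0,
                       n_pigment = 0, pale_mart1_fraction = 0,
                       dark_mart1_fraction = 0, noise_sd = 0, seed = 1,
                       lesion_polygon = cbind(c(50, 150, 150, 50),
                                              c(50, 50, 150, 150)))
  ph <- render_phantom(spec)
  outside <- !ph$truth$tumor_mask
  expect_true(all(ph$image$pixels[, , 1][outside] == 255))
  expect_identical(nrow(ph$truth$positive_centroids), 0L)
  expect_identical(nrow(ph$truth$confounder_centroids), 0L)
})

test_that("positive count is conserved and contained in the lesion", {
  spec <- small_spec(seed = 42, n_positive = 50, cluster_fraction = 0)
  ph <- render_phantom(spec)
  pc <- ph$truth$positive_centroids
  expect_identical(nrow(pc), 50L)
  expect_true(all(points_in_poly(pc$x_um, pc$y_um, spec$lesion_polygon)))
})

test_that("identical spec and seed give a bit-identical phantom", {
  spec <- small_spec(seed = 9)
  a <- render_phantom(spec)
  b <- render_phantom(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$positive_centroids, b$truth$positive_centroids)
  expect_identical(a$truth$tumor_mask, b$truth$tumor_mask)
})

test_that("render_phantom does not disturb the caller's RNG stream", {
  set.seed(123); before <- .Random.seed
  render_phantom(small_spec(seed = 4))
  expect_identical(.Random.seed, before)
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(width_um = -1), "positive")
  expect_error(phantom_spec(um_per_px = 0), "positive")
  expect_error(phantom_spec(phase_mix = c(0.5, 0.5, 0.2, 0)), "sum to 1")
  expect_error(phantom_spec(cluster_fraction = 1.2), "fractions")
  expect_error(phantom_spec(n_positive = -3), "counts")
  bowtie <- cbind(c(0, 100, 0, 100), c(0, 100, 100, 0))
  expect_error(phantom_spec(lesion_polygon = bowtie), "simple")
})

test_that("sampling respects cluster geometry and minimum distance", {
  spec <- small_spec(seed = 3, n_positive = 1)
  set.seed(1)
  expect_identical(nrow(sample_positions(spec)), 1L)

  ## degenerate cluster: everything lands on the planted centre
  tight <- small_spec(seed = 3, n_positive = 25, cluster_fraction = 1,
                      cluster_sd_um = 1)
  set.seed(2)
  pts <- sample_positions(tight, min_dist_um = 0)
  d <- sqrt((pts[, 1] - tight$cluster_center[1])^2 +
            (pts[, 2] - tight$cluster_center[2])^2)
  expect_true(all(d <= 10))

  ## min-distance enforcement
  spaced <- small_spec(seed = 3, n_positive = 30, cluster_fraction = 0)
  set.seed(4)
  pts <- sample_positions(spaced)
  dd <- as.matrix(dist(pts)); diag(dd) <- Inf
  expect_gte(min(dd), spaced$positive_min_dist_um)

  ## infeasible density errors out
  tiny <- phantom_spec(width_um = 100, height_um = 100, um_per_px = 2,
                       n_positive = 200,
                       lesion_polygon = cbind(c(30, 70, 70, 30),
                                              c(30, 30, 70, 70)),
                       cluster_fraction = 0, seed = 1)
  set.seed(5)
  expect_error(sample_positions(tiny), "infeasible")
})

test_that("planted cluster is recoverable by a densest-square oracle", {
  ## needs the full-size field: the 1-mm^2 square must fit inside it
  spec <- default_spec(seed = 21, n_positive = 40, cluster_fraction = 0.8,
                       cluster_sd_um = 150)
  ph <- render_phantom(spec)
  cen <- as.matrix(ph$truth$positive_centroids[, c("x_um", "y_um")])
  xs <- seq(0, spec$width_um, by = 10)
  ys <- seq(0, spec$height_um, by = 10)
  half <- 500
  best <- c(-1, NA, NA)
  for (gx in xs) for (gy in ys) {
    cnt <- sum(cen[, 1] >= gx - half & cen[, 1] < gx + half &
               cen[, 2] >= gy - half & cen[, 2] < gy + half)
    if (cnt > best[1]) best <- c(cnt, gx, gy)
  }
  d <- sqrt(sum((best[2:3] - ph$truth$planted_cluster_center)^2))
  expect_lte(d, 300)
})

test_that("rasterized tumor mask area matches the polygon area", {
  for (seed in 1:2) {
    spec <- small_spec(seed = seed)
    ph <- render_phantom(spec)
    mask_area <- sum(ph$truth$tumor_mask) * spec$um_per_px^2
    geo_area <- poly_area(spec$lesion_polygon)
    expect_gte(geo_area, 0.1e6)   # precondition of the invariant
    expect_lt(abs(mask_area - geo_area) / geo_area, 0.02)
  }
})

test_that("single pure stains concentrate OD in their own channel", {
  basis <- default_stain_basis()
  zero <- matrix(0, 20, 20)
  amt <- matrix(0.8, 20, 20)
  fields <- list(hematoxylin = list(amt, zero, zero),
                 dab = list(zero, amt, zero),
                 red = list(zero, zero, amt))
  for (stain in names(fields)) {
    f <- fields[[stain]]
    img <- calibrated_image(round(forward_beer_lambert(f[[1]], f[[2]], f[[3]],
                                                       basis)), 2)
    dens <- deconvolve(img, basis)
    tot <- sapply(dens, sum)
    expect_gte(tot[[stain]] / sum(tot), 0.95)
  }
})

test_that("phantom artifacts round-trip through the declared formats", {
  dir <- withr::local_tempdir()
  spec <- small_spec(seed = 6, n_positive = 10)
  ph <- render_phantom(spec)
  write_phantom(ph, dir)
  img <- read_image(file.path(dir, "phantom.png"))
  expect_equal(img$um_per_px, 2)
  expect_equal(img$pixels, ph$image$pixels, tolerance = 1e-6)
  cent <- read.csv(file.path(dir, "truth_centroids.csv"))
  expect_identical(sum(cent$kind == "positive"), 10L)
  poly <- read_polygon(file.path(dir, "lesion.geojson"))
  expect_equal(poly, unname(spec$lesion_polygon))
})
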