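make_cm <- function(labels, s = 1) {
  structure(list(labels = labels, um_per_px = s,
                 levels = c("BACKGROUND", "PHH3", "MART1", "HEMATOXYLIN")),
            class = "class_map")
}

test_that("chromatin fusion closes small gaps and keeps larger ones", {
  m <- matrix(0L, 20, 30)
  m[8:12, 5:8] <- 1L            # blob A, ends at column 8
  m[8:12, 12:15] <- 1L          # blob B after a 3-um gap (columns 9-11)
  expect_identical(fuse_chromatin(make_cm(m), 2)$n, 1L)

  m2 <- matrix(0L, 20, 30)
  m2[8:12, 3:5] <- 1L
  m2[8:12, 16:19] <- 1L         # 10-um gap
  expect_identical(fuse_chromatin(make_cm(m2), 2)$n, 2L)

  ## measurements are on the original pixels, not the dilated mask
  f <- fuse_chromatin(make_cm(m), 2)
  expect_identical(sum(f$labels > 0L), sum(m == 1L))
  expect_error(fuse_chromatin(make_cm(m), -1), ">= 0")
})

test_that("a phantom of anaphase figures fuses to exactly one object each", {
  spec <- phantom_spec(
    width_um = 1000, height_um = 1000, um_per_px = 1, n_positive = 20,
    n_tumor_nuclei = 0, n_lymphocytes = 0, n_pigment = 0,
    pale_mart1_fraction = 0, dark_mart1_fraction = 0, noise_sd = 0,
    phase_mix = c(prophase = 0, metaphase = 0, anaphase = 1, telophase = 0),
    chromatin_gap_um = 4, seed = 12)
  ph <- render_phantom(spec)
  cm <- classify_image(ph$image)
  expect_identical(fuse_chromatin(cm, 2.5)$n, 20L)
})

test_that("mart1_surround measures the perinuclear ring", {
  ## nucleus fully enclosed by red
  m <- matrix(0L, 30, 30)
  obj <- as.matrix(expand.grid(i = 13:17, j = 13:17))
  m[obj] <- 1L
  ring_all_red <- m
  ring_all_red[m == 0L] <- 2L
  idx <- which(m == 1L)
  expect_equal(mart1_surround(idx, make_cm(ring_all_red), 2), 1.0,
               tolerance = 0.05)

  ## isolated object on background
  expect_equal(mart1_surround(idx, make_cm(m), 2), 0.0)

  ## half-contact: the lower half-plane (through the object centre) is
  ## MART1, so about half the ring touches red
  half <- m
  half[m == 0L & row(m) >= 15] <- 2L
  fr <- mart1_surround(idx, make_cm(half), 2)
  expect_equal(fr, 0.5, tolerance = 0.1)

  expect_error(mart1_surround(idx, make_cm(m), 0), "> 0")
})

test_that("scoring gates act on each feature independently", {
  cfg <- default_config()
  base <- data.frame(x_um = 10, y_um = 10, area_um2 = 40,
                     mean_brown_od = 1.0, irregularity = 0.1,
                     mart1_surround_fraction = 0.9)
  vary <- rbind(
    base,                                        # passes all gates
    transform(base, area_um2 = 4),               # pigment-granule size
    transform(base, area_um2 = 400),             # aggregate size
    transform(base, mean_brown_od = 0.2),        # too faint
    transform(base, mart1_surround_fraction = 0.1),  # lymphocyte-like
    transform(base, irregularity = 0.9))         # speckled clump
  cells <- score_objects(vary, cfg)
  expect_identical(cells$positive, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(attr(cells, "config_hash"), config_hash(cfg))
})

test_that("tumor area assembles MART1, reclassified nuclei and holes", {
  cfg <- default_config()
  ## nothing stained inside the outline
  empty <- make_cm(matrix(0L, 50, 50), 20)
  sq <- cbind(c(100, 900, 900, 100), c(100, 100, 900, 900))
  expect_equal(tumor_area(empty, sq, config = cfg)$area_mm2, 0)

  ## solid 1 mm x 1 mm of red at 2 um/px
  m <- matrix(0L, 700, 700)
  m[101:600, 101:600] <- 2L
  tm <- tumor_area(make_cm(m, 2), config = cfg)
  expect_equal(tm$area_mm2, 1.0, tolerance = 0.01)
  expect_identical(tm$area_mm2, sum(tm$mask) * 4 / 1e6)

  ## a blue nucleus inside red joins the mask; an isolated one does not
  m2 <- matrix(0L, 100, 100)
  m2[21:80, 21:80] <- 2L
  m2[45:52, 45:52] <- 3L                       # nucleus in red, ~256 um2
  m2[5:12, 5:12] <- 3L                         # isolated nucleus outside
  tm2 <- tumor_area(make_cm(m2, 2), config = cfg)
  expect_true(all(tm2$mask[45:52, 45:52]))
  expect_false(any(tm2$mask[5:12, 5:12]))
})

test_that("phantom tumor mask overlaps truth (Jaccard >= 0.85)", {
  spec <- default_spec(seed = 7)
  ph <- render_phantom(spec)
  det <- detect_cells(ph$image, spec$lesion_polygon)
  inter <- sum(det$tumor$mask & ph$truth$tumor_mask)
  uni <- sum(det$tumor$mask | ph$truth$tumor_mask)
  expect_gte(inter / uni, 0.85)
})

test_that("detect_cells finds exactly the planted cells on clean phantoms", {
  img <- calibrated_image(array(255, c(50, 50, 3)), 2)
  det <- detect_cells(img)
  expect_identical(nrow(det$cells), 0L)
  expect_equal(det$tumor$area_mm2, 0)

  spec <- clean_spec(seed = 5, um_per_px = 1, n_tumor_nuclei = 60)
  ph <- render_phantom(spec)
  det <- detect_cells(ph$image, spec$lesion_polygon)
  expect_identical(sum(det$cells$positive),
                   nrow(ph$truth$positive_centroids))
  m <- match_centroids(positive_centroids(det$cells),
                       as.matrix(ph$truth$positive_centroids[, 1:2]))
  expect_identical(m$fp, 0L)
  expect_identical(m$fn, 0L)
})

test_that("adding an exclusion polygon never increases counts or area", {
  spec <- small_spec(seed = 14)
  ph <- render_phantom(spec)
  det0 <- detect_cells(ph$image, spec$lesion_polygon)
  excl <- list(cbind(c(200, 600, 600, 200), c(200, 200, 600, 600)))
  det1 <- detect_cells(ph$image, spec$lesion_polygon, excl)
  expect_lte(sum(det1$cells$positive), sum(det0$cells$positive))
  expect_lte(det1$tumor$area_mm2, det0$tumor$area_mm2)
})

test_that("counts are stable under whole-pixel translation", {
  spec <- clean_spec(seed = 19)
  ph <- render_phantom(spec)
  det0 <- detect_cells(ph$image, spec$lesion_polygon)
  s <- spec$um_per_px
  px <- ph$image$pixels
  shifted <- px
  shifted[, 2:ncol(px), ] <- px[, 1:(ncol(px) - 1), ]
  shifted[, 1, ] <- 255
  poly2 <- spec$lesion_polygon
  poly2[, 1] <- poly2[, 1] + s
  det1 <- detect_cells(calibrated_image(shifted, s), poly2)
  expect_identical(sum(det1$cells$positive), sum(det0$cells$positive))
})

test_that("pigment-only phantoms yield zero positives", {
  spec <- small_spec(seed = 13, n_positive = 0, n_lymphocytes = 0,
                     pale_mart1_fraction = 0, dark_mart1_fraction = 0,
                     n_pigment = 12)
  ph <- render_phantom(spec)
  det <- detect_cells(ph$image, spec$lesion_polygon)
  expect_identical(sum(det$cells$positive), 0L)
})

test_that("lymphocytes outside MART1 are scored negative", {
  spec <- small_spec(seed = 4, n_positive = 0, n_pigment = 0,
                     pale_mart1_fraction = 0, dark_mart1_fraction = 0,
                     n_lymphocytes = 6)
  ph <- render_phantom(spec)
  det <- detect_cells(ph$image)    # whole frame: lymphocytes visible
  expect_identical(sum(det$cells$positive), 0L)
  expect_gt(nrow(det$cells), 0L)   # but they are detected as objects
})

test_that("greedy matching is one-to-one within tolerance", {
  det <- rbind(c(0, 0), c(10, 0), c(100, 100))
  tru <- rbind(c(1, 0), c(11, 0), c(50, 50))
  m <- match_centroids(det, tru, tol_um = 5)
  expect_identical(m$tp, 2L)
  expect_identical(m$fp, 1L)
  expect_identical(m$fn, 1L)
  ## two detections cannot claim one truth
  m2 <- match_centroids(rbind(c(0, 0), c(1, 0)), rbind(c(0.5, 0)), tol_um = 5)
  expect_identical(m2$tp, 1L)
  expect_identical(m2$fp, 1L)
})
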