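bbox_domain <- c(0, 0, 1500, 1500)

test_that("heat map counts cells within the circle radius", {
  hm0 <- build_heatmap(matrix(numeric(0), ncol = 2), bbox_domain, 200, 50)
  expect_true(all(hm0$intensity == 0L))

  hm1 <- build_heatmap(rbind(c(500, 500)), bbox_domain, 200, 50)
  g <- expand.grid(y = hm1$ys, x = hm1$xs)
  within <- (g$x - 500)^2 + (g$y - 500)^2 <= 200^2
  expect_identical(as.vector(hm1$intensity == 1L), within)

  ## two cells 300 um apart: max 2 exactly where both circles overlap
  cen <- rbind(c(600, 700), c(900, 700))
  hm2 <- build_heatmap(cen, bbox_domain, 200, 25)
  g2 <- expand.grid(y = hm2$ys, x = hm2$xs)
  both <- with(g2, (x - 600)^2 + (y - 700)^2 <= 200^2 &
                   (x - 900)^2 + (y - 700)^2 <= 200^2)
  expect_identical(max(hm2$intensity), 2L)
  expect_identical(as.vector(hm2$intensity == 2L), both)

  expect_error(build_heatmap(cen, c(0, 0, 0, 0), 200, 10), "empty")
  expect_error(build_heatmap(cen, bbox_domain, -1, 10), "positive")
})

test_that("heat map equals the brute-force oracle on random cell sets", {
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(1:60, 1)
    cen <- cbind(runif(n, 0, 1500), runif(n, 0, 1500))
    hm <- build_heatmap(cen, bbox_domain, 200, 60)
    expect_identical(hm$intensity,
                     oracle_circle_counts(cen, hm$xs, hm$ys, 200))
  }
})

test_that("hot-spot selection returns the argmax with deterministic ties", {
  ## single cell: centre within the circle radius of it, peak 1
  hm <- build_heatmap(rbind(c(700, 800)), bbox_domain, 200, 10)
  hs <- select_hotspot(hm)
  expect_identical(hs$peak_intensity, 1L)
  expect_lte(sqrt(sum((hs$center - c(700, 800))^2)), 200)
  expect_identical(hs$count, 1L)
  expect_equal(hs$square, unname(c(hs$center[1] - 500, hs$center[2] - 500,
                                   hs$center[1] + 500, hs$center[2] + 500)))

  ## no cells: distinguished no-hot-spot outcome
  hm0 <- build_heatmap(matrix(numeric(0), ncol = 2), bbox_domain, 200, 50)
  expect_null(select_hotspot(hm0))

  ## two equal, far-apart clusters: tie broken deterministically
  cen <- rbind(c(200, 200), c(1300, 1300))
  hm2 <- build_heatmap(cen, bbox_domain, 200, 20)
  a <- select_hotspot(hm2)
  b <- select_hotspot(hm2)
  expect_identical(a$center, b$center)
  expect_identical(a$peak_intensity, 1L)
  ## scan-order rule: the component containing (200, 200) comes first
  expect_lte(sqrt(sum((a$center - c(200, 200))^2)), 200)
})

test_that("exclusion polygons make grid centres ineligible", {
  cen <- rbind(c(400, 400), c(410, 400), c(1200, 1200))
  hm <- build_heatmap(cen, bbox_domain, 200, 20)
  hs <- select_hotspot(hm)
  expect_identical(hs$peak_intensity, 2L)
  ## exclude the dominant cluster region entirely
  excl <- list(cbind(c(0, 700, 700, 0), c(0, 0, 700, 700)))
  hs2 <- select_hotspot(hm, exclusions = excl)
  expect_lte(sqrt(sum((hs2$center - c(1200, 1200))^2)), 200)
})

test_that("count_in_square is half-open and respects exclusions", {
  sq <- c(100, 100, 1100, 1100)
  expect_identical(count_in_square(matrix(numeric(0), ncol = 2), sq), 0L)
  cen <- rbind(c(100, 500),    # left edge: in
               c(1100, 500),   # right edge: out
               c(500, 100),    # top edge: in
               c(500, 1100),   # bottom edge: out
               c(500, 500))
  expect_identical(count_in_square(cen, sq), 3L)
  excl <- list(cbind(c(400, 600, 600, 400), c(400, 400, 600, 600)))
  expect_identical(count_in_square(cen, sq, excl), 2L)

  ## planted fixture: 12 cells inside a known square
  set.seed(3)
  inside <- cbind(runif(12, 300, 900), runif(12, 300, 900))
  outside <- cbind(runif(7, 1200, 1400), runif(7, 1200, 1400))
  expect_identical(count_in_square(rbind(inside, outside),
                                   c(200, 200, 1200, 1200)), 12L)
})

test_that("selected square matches the square-placement oracle", {
  set.seed(101)
  for (rep in 1:3) {
    spec <- default_spec(seed = 300 + rep)
    pts <- sample_positions(spec)
    hm <- build_heatmap(pts, bbox_domain, 200, 10)
    hs <- select_hotspot(hm, selector = "square")
    expect_identical(hs$count, oracle_square_max(pts, hm$xs, hm$ys))
    ## dominance: the oracle square beats every candidate placement
    for (gx in hm$xs[seq(1, length(hm$xs), by = 10)])
      for (gy in hm$ys[seq(1, length(hm$ys), by = 10)])
        expect_gte(hs$count, count_in_square(
          pts, c(gx - 500, gy - 500, gx + 500, gy + 500)))
  }
})

test_that("adding a cell never decreases peak intensity", {
  set.seed(55)
  cen <- cbind(runif(40, 0, 1500), runif(40, 0, 1500))
  p1 <- max(build_heatmap(cen, bbox_domain, 200, 30)$intensity)
  for (rep in 1:5) {
    extra <- rbind(cen, c(runif(1, 0, 1500), runif(1, 0, 1500)))
    p2 <- max(build_heatmap(extra, bbox_domain, 200, 30)$intensity)
    expect_gte(p2, p1)
  }
})

test_that("overlap categories follow the distance bands", {
  cat_of <- function(dx, dy)
    categorize_overlap(c(0, 0), c(dx, dy), units = "mm")$category
  expect_identical(cat_of(0, 0), "PERFECT")
  expect_identical(cat_of(0.5, 0.2), "MAYOR")    # printed band 0.10-0.74
  expect_identical(cat_of(1.2, 0), "NONE")       # squares disjoint
  expect_identical(cat_of(0.099, 0.099), "PERFECT")
  expect_identical(cat_of(0.10, 0), "MAYOR")
  expect_identical(cat_of(0.74, 0), "MAYOR")
  expect_identical(cat_of(0.75, 0), "MINOR")
  expect_identical(cat_of(1.0, 0), "MINOR")
  expect_identical(cat_of(1.0001, 0), "NONE")
  ## category is driven by the larger coordinate distance
  expect_identical(cat_of(0.05, 0.8), "MINOR")
})

test_that("category NONE coincides exactly with disjoint squares", {
  ## closed unit squares centred dx, dy apart intersect iff both
  ## coordinate distances are <= 1 (at exactly 1 they share an edge)
  vals <- (0:26) / 20   # 0 to 1.3 in exact 0.05 steps
  for (dx in vals) for (dy in vals) {
    r <- categorize_overlap(c(0, 0), c(dx, dy), units = "mm")
    expect_identical(r$category == "NONE", !(dx <= 1 && dy <= 1),
                     info = sprintf("dx=%g dy=%g", dx, dy))
  }
})
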