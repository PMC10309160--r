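test_that("smallest enclosing circle on known configurations", {
  f <- min_circumscribed_circle(rbind(c(0, 0), c(2, 0)))
  expect_equal(f$center, c(1, 0))
  expect_equal(f$radius, 1)
  # equilateral triangle, side 2: circumradius 2/sqrt(3)
  tri <- rbind(c(0, 0), c(2, 0), c(1, sqrt(3)))
  expect_equal(min_circumscribed_circle(tri)$radius, 2 / sqrt(3),
               tolerance = 1e-12)
  # unit square corners: half diagonal
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(min_circumscribed_circle(sq)$radius, sqrt(2) / 2,
               tolerance = 1e-12)
  expect_equal(min_circumscribed_circle(matrix(c(3, 4), 1))$radius, 0)
  expect_error(min_circumscribed_circle(matrix(numeric(0), 0, 2)), "point")
})

test_that("solver matches the O(n^3) enumeration oracle on random sets", {
  set.seed(314)
  for (i in 1:25) {
    n <- sample(3:50, 1)
    pts <- cbind(runif(n, -10, 10), rnorm(n, sd = 4))
    got <- min_circumscribed_circle(pts)
    ref <- brute_force_mec(pts)
    expect_equal(got$radius, ref[3], tolerance = 1e-9)
    d <- sqrt((pts[, 1] - got$center[1])^2 + (pts[, 2] - got$center[2])^2)
    expect_true(all(d <= got$radius * (1 + 1e-9) + 1e-9))
  }
})

test_that("maximum inscribed circle finds the incircle of simple masks", {
  mc <- max_inscribed_circle(rasterize(make_circle(50)))
  expect_equal(mc$radius, 50, tolerance = 1)
  expect_lt(sqrt(sum(mc$center^2)), 1)
  sp <- shape_spec("ellipse", sqrt(100 * 40), axis_ratio = 0.4)
  me <- max_inscribed_circle(rasterize(contour_from_spec(sp)))
  expect_equal(me$radius, 40, tolerance = 1.5)
  # square of side 21: half side
  sq <- as_contour(cbind(c(-10.5, 10.5, 10.5, -10.5),
                         c(-10.5, -10.5, 10.5, 10.5)) + 0.01)
  ms <- max_inscribed_circle(rasterize(sq))
  expect_equal(ms$radius, 10.5, tolerance = 1)
  expect_error(max_inscribed_circle(faz_mask(matrix(0L, 4, 4))),
               "no foreground")
})

test_that("MIC boundary references are ordered consistently", {
  m <- rasterize(make_circle(40))
  r_bgc <- max_inscribed_circle(m, "background_centers")$radius
  r_crk <- max_inscribed_circle(m, "crack")$radius
  r_bc <- max_inscribed_circle(m, "boundary_centers")$radius
  # background centers are ~0.5 px beyond the crack, which is ~0.5 px beyond
  # the boundary pixel centers
  expect_gt(r_bgc, r_crk)
  expect_gt(r_crk, r_bc - 0.2)
  expect_true(all(abs(c(r_bgc, r_crk, r_bc) - 40) < 1.2))
})

test_that("contour-domain MIC recovers the ellipse semi-minor axis", {
  sp <- shape_spec("ellipse", 10, axis_ratio = 0.4)
  mic <- max_inscribed_circle_contour(contour_from_spec(sp))
  expect_equal(mic$radius, sp$semi_minor, tolerance = 0.01)
})

test_that("MIC/MCC roundness definition and ideal values", {
  mic <- circle_fit(c(0, 0), 4, "inscribed")
  mcc <- circle_fit(c(0, 0), 10, "circumscribed")
  expect_equal(mic_mcc_roundness(mic, mcc), 0.16)
  expect_equal(mic_mcc_roundness(circle_fit(c(0, 0), 7, "inscribed"),
                                 circle_fit(c(0, 0), 7, "circumscribed")), 1)
  # square: (half side / half diagonal)^2 = 1/2
  expect_equal(mic_mcc_roundness(circle_fit(c(0, 0), 0.5, "inscribed"),
                                 circle_fit(c(0, 0), sqrt(2) / 2, "circumscribed")),
               0.5, tolerance = 1e-12)
  expect_error(mic_mcc_roundness(mcc, mic), "inscribed")
  expect_error(mic_mcc_roundness(mic, circle_fit(c(0, 0), 0, "circumscribed")),
               "positive")
})

test_that("MIC and MCC nest around the pixel region", {
  for (seed in c(1, 6)) {
    m <- rasterize(make_faz_blob(seed = seed, mean_radius = 22,
                                 irregularity = 0.25))
    mic <- max_inscribed_circle(m)
    mcc <- min_circumscribed_circle_mask(m)
    # no background pixel center strictly inside the MIC
    bg <- fazmetrics:::background_boundary_centers(m)
    bgxy <- cbind(m$origin[1] + bg[, 1] - 1, m$origin[2] + bg[, 2] - 1)
    dmin <- min(sqrt((bgxy[, 1] - mic$center[1])^2 +
                     (bgxy[, 2] - mic$center[2])^2))
    expect_gte(dmin, mic$radius - 1e-6)
    # every foreground pixel center inside the MCC
    idx <- which(m$grid == 1L, arr.ind = TRUE)
    fx <- m$origin[1] + idx[, 2] - 1; fy <- m$origin[2] + idx[, 1] - 1
    dmax <- max(sqrt((fx - mcc$center[1])^2 + (fy - mcc$center[2])^2))
    expect_lte(dmax, mcc$radius + 1e-6)
  }
})
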