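test_that("region area counts foreground pixels", {
  expect_equal(region_area(block_mask(3, 3)), 9L)
  expect_equal(region_area(upsample_mask(block_mask(3, 3), 2L)), 36L)
  expect_error(region_area(faz_mask(matrix(0L, 3, 3))), "no foreground")
})

test_that("Moore boundary tracing is canonical and complete", {
  # single pixel: a path of just itself
  s <- faz_mask(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3))
  expect_equal(nrow(trace_boundary(s)), 1L)
  # 3x3 block: all 8 ring pixels, interior excluded
  path <- trace_boundary(block_mask(3, 3))
  expect_equal(nrow(unique(path)), 8L)
  expect_false(any(path[, 1] == 3 & path[, 2] == 3))  # center (row 3, col 3 w/ pad)
  # 1x5 line: 5 boundary pixels, traversed out and back
  line <- block_mask(1, 5)
  lp <- trace_boundary(line)
  expect_equal(nrow(unique(lp)), 5L)
  expect_equal(nrow(lp), 8L)
  # multiple components are rejected
  g <- matrix(0L, 5, 5); g[2, 2] <- 1L; g[4, 4] <- 1L
  expect_error(trace_boundary(faz_mask(g)), "component")
})

test_that("chain-code perimeter on hand-traced masks", {
  expect_equal(perimeter_chain8(block_mask(3, 3)), 8)
  s <- faz_mask(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3))
  expect_equal(perimeter_chain8(s), 0)
  # 2x2 block: the canonical clockwise Moore trace walks the 4 pixels with
  # axial steps
  expect_equal(perimeter_chain8(block_mask(2, 2)), 4)
})

test_that("corner-weighted perimeter uses the configured weights", {
  # 3x3 block: 8 axial steps, 4 direction changes
  expect_equal(perimeter_corner_weighted(block_mask(3, 3)),
               0.980 * 8 - 0.091 * 4)
  # weight degeneracy: (1, sqrt(2), 0) reproduces the chain-code length
  for (m in list(block_mask(3, 5), rasterize(make_circle(9)),
                 rasterize(make_faz_blob(seed = 3, mean_radius = 15)))) {
    expect_equal(perimeter_corner_weighted(m, weights = c(1, sqrt(2), 0)),
                 perimeter_chain8(m))
  }
})

test_that("crack outline walking counts edges and corners", {
  s <- faz_mask(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3))
  cp1 <- crack_polygon(s)
  expect_equal(cp1$n_edges, 4L)
  expect_equal(length(cp1$run_lengths), 4L)
  cp3 <- crack_polygon(block_mask(3, 3))
  expect_equal(cp3$n_edges, 12L)
  expect_equal(sort(cp3$run_lengths), rep(3L, 4))
  # vertices trace a closed axis-aligned square of side 3
  expect_equal(diff(range(cp3$vertices[, 1])), 3)
})

test_that("traced perimeter reproduces its configured corner rules", {
  s <- faz_mask(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3))
  # particle-analysis rule: 4 unit edges, alternating corner count = 2
  expect_equal(perimeter_traced(s), 0.948 * 4 + (1.340 - 2 * 0.948) * 2)
  expect_equal(perimeter_traced(block_mask(3, 3)),
               0.948 * 12 + (1.340 - 2 * 0.948) * 4)
  # plain crack length minus (2 - sqrt(2)) per convex corner
  expect_equal(perimeter_traced(s, style = "corner_deficit"), 4 * sqrt(2) - 4)
  expect_equal(perimeter_traced(block_mask(3, 3), style = "corner_deficit"),
               12 - 4 * (2 - sqrt(2)))
})

test_that("perimeter estimators are near-unbiased or biased as designed", {
  r <- 200
  m <- rasterize(make_circle(r))
  truth <- 2 * pi * r
  expect_lt(abs(perimeter_corner_weighted(m) - truth) / truth, 0.005)
  expect_lt(abs(perimeter_traced(m) - truth) / truth, 0.02)
  # chain code over-measures smooth boundaries by roughly 5 %
  expect_gt(perimeter_chain8(m) / truth, 1.02)
  expect_lt(perimeter_chain8(m) / truth, 1.08)
})

test_that("moment ellipse fit recovers ideal axes and conventions agree", {
  sp <- shape_spec("ellipse", sqrt(100 * 40), axis_ratio = 0.4)
  expect_equal(sp$semi_major, 100, tolerance = 1e-12)
  m <- rasterize(contour_from_spec(sp))
  fit <- fit_ellipse_moments(m)
  expect_equal(fit$major_axis, 200, tolerance = 0.01)
  expect_equal(fit$minor_axis, 80, tolerance = 0.01)
  fit_ea <- fit_ellipse_moments(m, "equal_area")
  expect_equal(fit_ea$minor_axis / fit_ea$major_axis,
               fit$minor_axis / fit$major_axis, tolerance = 1e-9)
  # disk: near-identical axes (the pixel-center fill rule leaves a
  # sub-pixel asymmetry, so the ratio is close to but not exactly 1)
  fd <- fit_ellipse_moments(rasterize(make_circle(30)))
  expect_equal(fd$major_axis / fd$minor_axis, 1, tolerance = 2e-3)
})

test_that("AR roundness is the axis ratio", {
  fit <- structure(list(major_axis = 10, minor_axis = 4, orientation = 0,
                        convention = "moment_normalized"),
                   class = "ellipse_fit")
  expect_equal(ar_roundness(fit), 0.4)
  expect_equal(ar_roundness(rasterize(make_circle(25))), 1, tolerance = 2e-3)
})

test_that("software circularity conventions behave as documented", {
  big <- rasterize(make_circle(150))
  expect_equal(software_circularity(big, "matlab_style"), 1, tolerance = 0.01)
  # particle-analysis-style circularity of a large digital disk sits near
  # 0.9 because its denominator is the biased chain-code perimeter
  cij <- software_circularity(big, "imagej_style")
  expect_gt(cij, 0.85); expect_lt(cij, 0.95)
  # small regions: uncorrected ratio exceeds 1, the imagej cap clamps
  b3 <- block_mask(3, 3)
  expect_equal(software_circularity(b3, "matlab_style",
                                    apply_small_region_correction = FALSE),
               4 * pi * 9 / (0.980 * 8 - 0.091 * 4)^2)  # about 2.023
  expect_lte(software_circularity(b3, "imagej_style"), 1)
  # the optional matlab-style correction shrinks small-region circularity
  expect_lt(software_circularity(b3, "matlab_style",
                                 apply_small_region_correction = TRUE),
            software_circularity(b3, "matlab_style",
                                 apply_small_region_correction = FALSE))
})

test_that("region area is invariant under translation and rotation", {
  b <- rasterize(make_faz_blob(seed = 9, mean_radius = 14, irregularity = 0.2))
  a <- region_area(b)
  expect_equal(region_area(faz_mask(t(b$grid[nrow(b$grid):1, ]))), a)  # 90 deg
  shifted <- faz_mask(b$grid, origin = b$origin + c(17, -4))
  expect_equal(region_area(shifted), a)
})
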