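test_that("make_circle samples exact circle points", {
  p <- make_circle(10)
  expect_equal(nrow(p), 300L)
  expect_true(all(abs(sqrt(rowSums(p^2)) - 10) < 1e-12))
  p2 <- make_circle(2, center = c(0, 0))
  expect_equal(unname(p2[1, ]), c(2, 0))  # t = 0
  # shoelace area of the inscribed regular n-gon
  expect_equal(polygon_area(p), 0.5 * 300 * 10^2 * sin(2 * pi / 300),
               tolerance = 1e-12)
  expect_error(make_circle(-1), "positive")
  expect_error(make_circle(5, n_samples = 2), "at least 3")
})

test_that("same-area ellipses have the prescribed axes and area", {
  es <- make_same_area_ellipses(10, ratios = c(0.4, 0.6, 0.8))
  expect_length(es, 3L)
  e4 <- es[["0.4"]]
  a <- max(e4[, 1]); b <- max(e4[, 2])
  expect_equal(a, 10 / sqrt(0.4), tolerance = 1e-9)  # 15.8114
  expect_equal(b, 10 * sqrt(0.4), tolerance = 1e-9)  # 6.3246
  expect_equal(a * b, 100, tolerance = 1e-9)
  # degenerate ratio 1 reduces to the circle
  expect_equal(unclass(make_same_area_ellipses(10, ratios = 1)[[1]]),
               unclass(make_circle(10)))
  expect_error(make_same_area_ellipses(10, ratios = c(0.5, 1.2)), "ratio")
})

test_that("battery generation yields the configured shape set", {
  shapes <- generate_battery()
  expect_length(shapes, 148L)
  kinds <- vapply(shapes, function(s) s$spec$kind, "")
  expect_equal(sum(kinds == "circle"), 37L)
  radii <- vapply(shapes, function(s) s$spec$reference_radius, 0)
  expect_equal(min(radii), 2)
  expect_equal(max(radii), 1000)
  expect_length(generate_battery(radii = 5, ratios = numeric(0)), 1L)
  expect_error(battery_radii(10, 5, 3), "at least")
})

test_that("same-area construction carries over to the polygon areas", {
  # both circle and ellipse 300-gons have the identical inscribed-polygon
  # area deficit, so their shoelace areas agree almost exactly
  shapes <- generate_battery(radii = c(3, 47.3), ratios = c(0.4, 0.6, 0.8))
  areas <- vapply(shapes, function(s) polygon_area(s$contour), 0)
  for (grp in split(areas, rep(1:2, each = 4))) {
    expect_true(all(abs(grp - grp[1]) / grp[1] < 1e-4))
  }
})

test_that("FAZ blob generator is seeded, smooth and validated", {
  b1 <- make_faz_blob(seed = 7)
  b2 <- make_faz_blob(seed = 7)
  expect_identical(b1, b2)
  expect_false(identical(b1, make_faz_blob(seed = 8)))
  # zero irregularity degenerates to the circle
  b0 <- make_faz_blob(seed = 1, mean_radius = 20, irregularity = 0)
  expect_equal(sqrt(rowSums(b0^2)), rep(20, nrow(b0)), tolerance = 1e-12)
  # a perturbed blob is less circular than a circle
  b <- make_faz_blob(seed = 1, mean_radius = 50, irregularity = 0.2)
  expect_lt(circularity(polygon_area(b), polygon_perimeter(b)), 1)
  expect_error(make_faz_blob(1, irregularity = 0.5), "irregularity")
  expect_error(make_faz_blob(1, mean_radius = 1.5), "mean_radius")
  # the private RNG stream must not disturb the caller's
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(make_faz_blob(seed = 3)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("contour validation rejects malformed input", {
  expect_error(as_contour(cbind(c(0, 1), c(0, 1))), "3 vertices")
  expect_error(as_contour(cbind(c(0, 0, 1), c(0, 0, 1))), "duplicate")
  expect_error(as_contour(cbind(c(0, NA, 1), c(0, 1, 2))), "finite")
})
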