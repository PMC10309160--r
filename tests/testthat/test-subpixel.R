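test_that("shoelace area and distance-formula perimeter on known polygons", {
  sq <- as_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_perimeter(sq), 4)
  p <- make_circle(10)
  expect_equal(polygon_perimeter(p), 2 * 300 * 10 * sin(pi / 300),
               tolerance = 1e-12)
  # orientation invariance
  rev_p <- as_contour(p[nrow(p):1, ])
  expect_equal(polygon_area(rev_p), polygon_area(p))
  expect_equal(polygon_perimeter(rev_p), polygon_perimeter(p))
  # homogeneity under scaling
  expect_equal(polygon_perimeter(as_contour(3.7 * unclass(p))),
               3.7 * polygon_perimeter(p))
})

test_that("area and perimeter are rigid-motion invariant", {
  set.seed(42)
  b <- make_faz_blob(seed = 5, mean_radius = 30, irregularity = 0.25)
  a0 <- polygon_area(b); p0 <- polygon_perimeter(b)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    shift <- runif(2, -50, 50)
    moved <- as_contour(sweep(unclass(b) %*% R, 2, -shift))
    expect_equal(polygon_area(moved), a0, tolerance = 1e-9)
    expect_equal(polygon_perimeter(moved), p0, tolerance = 1e-9)
  }
})

test_that("theoretical measures use closed forms and exact quadrature", {
  th <- theoretical_measures(shape_spec("circle", 10))
  expect_equal(th$area, pi * 100)
  expect_equal(th$perimeter, 2 * pi * 10)
  # ellipse arc length cross-checked against the Ramanujan II closed form
  expect_equal(ellipse_arc_length(2, 1), 9.688448, tolerance = 1e-6)
  expect_equal(ellipse_arc_length(2, 1), ramanujan_perimeter(2, 1),
               tolerance = 1e-6)
  # a = b degenerates to the circle formulas
  sp <- shape_spec("ellipse", 7, axis_ratio = 1)
  expect_equal(theoretical_measures(sp)$perimeter, 2 * pi * 7,
               tolerance = 1e-10)
})

test_that("circularity variants and their known values", {
  expect_equal(circularity(pi * 25, 2 * pi * 5), 1)
  expect_equal(circularity(1, 4), pi / 4)
  expect_equal(circularity(1, 4, "iso_sqrt"), sqrt(pi / 4))
  p <- make_circle(10)
  expect_equal(circularity(polygon_area(p), polygon_perimeter(p)),
               0.999963, tolerance = 1e-6)
  expect_error(circularity(-1, 4), "positive")
})

test_that("circularity, AR roundness and the major axis obey the identity", {
  # for an ideal ellipse: circularity = AR * pi^2 * (2a)^2 / P^2
  for (q in c(0.4, 0.6, 0.8, 1)) {
    sp <- shape_spec(if (q == 1) "circle" else "ellipse", 10, axis_ratio = q)
    th <- theoretical_measures(sp)
    circ <- circularity(th$area, th$perimeter)
    expect_equal(circ, q * pi^2 * (2 * sp$semi_major)^2 / th$perimeter^2,
                 tolerance = 1e-9)
  }
})

test_that("percent difference is symmetric, non-negative and exact", {
  expect_equal(percent_difference(11, 9), 20)
  expect_equal(percent_difference(3, 1), 100)
  expect_equal(percent_difference(5.5, 5.5), 0)
  expect_equal(percent_difference(9, 11), percent_difference(11, 9))
  expect_error(percent_difference(1, -1), "undefined")
})

test_that("regular polygons approach circularity 1 from below", {
  prev <- 0
  for (n in c(8, 32, 128, 512)) {
    p <- make_circle(10, n_samples = n)
    cc <- circularity(polygon_area(p), polygon_perimeter(p))
    expect_lt(cc, 1)
    expect_gt(cc, prev)
    prev <- cc
  }
})
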