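#' Sub-pixel polygon area (shoelace formula)
#'
#' Area enclosed by the closed polygon of exact boundary coordinates.
#' Independent of traversal direction and starting vertex.
#'
#' @param contour A [as_contour()] matrix (>= 3 vertices, simple).
#' @return Area in px^2.
#' @export
polygon_area <- function(contour) {
  p <- as_contour(contour)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Sub-pixel polygon perimeter (distance formula)
#'
#' Sum of Euclidean vertex-to-vertex distances including the closing edge.
#'
#' @inheritParams polygon_area
#' @return Perimeter in px.
#' @export
polygon_perimeter <- function(contour) {
  p <- as_contour(contour)
  d <- p[c(2:nrow(p), 1L), , drop = FALSE] - p
  sum(sqrt(rowSums(d^2)))
}

#' Exact ellipse arc length
#'
#' Adaptive quadrature of the parametric speed
#' `sqrt(a^2 sin^2 t + b^2 cos^2 t)` over one period, to 1e-12 relative
#' tolerance (one quadrant, by symmetry).
#'
#' @param a,b Semi-axes (px).
#' @return Arc length in px.
#' @export
ellipse_arc_length <- function(a, b) {
  stopifnot(a > 0, b > 0)
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-12,
                       subdivisions = 1000L)$value
}

#' Theoretical (continuous-geometry) area and perimeter of a shape_spec
#'
#' Circles use the closed forms `pi r^2`, `2 pi r`; ellipses use `pi a b` and
#' the exact arc length by numerical quadrature.
#'
#' @param spec A [shape_spec()].
#' @return A list with `area` (px^2) and `perimeter` (px).
#' @export
theoretical_measures <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  if (spec$kind == "circle" || spec$semi_major == spec$semi_minor) {
    r <- spec$reference_radius
    list(area = pi * r^2, perimeter = 2 * pi * r)
  } else {
    list(area = pi * spec$semi_major * spec$semi_minor,
         perimeter = ellipse_arc_length(spec$semi_major, spec$semi_minor))
  }
}

#' Circularity from area and perimeter
#'
#' The standard definition is `4 pi A / P^2`, equal to 1 for an ideal circle
#' and below 1 for any other simple closed shape (isoperimetric inequality).
#' The ISO 9276-6 form is its square root. No capping is applied here; the
#' cap at 1.0 is a particle-analysis software convention, see
#' [software_circularity()].
#'
#' @param area Area (> 0).
#' @param perimeter Perimeter (> 0).
#' @param variant `"standard"` (4 pi A / P^2) or `"iso_sqrt"` (its square root).
#' @return Dimensionless circularity.
#' @export
circularity <- function(area, perimeter, variant = c("standard", "iso_sqrt")) {
  variant <- match.arg(variant)
  if (any(area <= 0) || any(perimeter <= 0))
    stop("area and perimeter must be positive")
  c0 <- 4 * pi * area / perimeter^2
  if (variant == "standard") c0 else sqrt(c0)
}

#' Symmetric percent difference
#'
#' `|a - b| / ((a + b) / 2) * 100`. Symmetric in its arguments and always
#' non-negative.
#'
#' @param a,b Values in the same units; `a + b` must be nonzero.
#' @return Percent difference.
#' @export
percent_difference <- function(a, b) {
  if (any(a + b == 0)) stop("percent difference undefined when a + b = 0")
  abs(a - b) / ((a + b) / 2) * 100
}
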