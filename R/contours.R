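#' Sub-pixel contours
#'
#' A contour is an ordered, closed list of sub-pixel `(x, y)` vertices stored
#' as a two-column numeric matrix of class `"faz_contour"`. The closing edge
#' (last vertex back to the first) is implicit; the first vertex is not
#' repeated. Coordinates are in pixel units with pixel centers at integer
#' positions, x increasing rightwards and y downwards.
#'
#' @param xy A two-column numeric matrix (or data frame) of vertices.
#' @return A `"faz_contour"` matrix.
#' @export
as_contour <- function(xy) {
  if (is.data.frame(xy)) xy <- as.matrix(xy)
  if (!is.matrix(xy) || ncol(xy) != 2L || !is.numeric(xy))
    stop("a contour must be a two-column numeric matrix of (x, y) vertices")
  if (nrow(xy) < 3L)
    stop("a contour needs at least 3 vertices")
  if (any(!is.finite(xy)))
    stop("contour vertices must be finite")
  dup <- rowSums(abs(xy - xy[c(2:nrow(xy), 1L), , drop = FALSE])) == 0
  if (any(dup))
    stop("contour has consecutive duplicate vertices")
  colnames(xy) <- c("x", "y")
  class(xy) <- c("faz_contour", class(unclass(xy)))
  xy
}

#' @export
print.faz_contour <- function(x, ...) {
  cat(sprintf("<faz_contour> %d vertices, bbox x [%.3g, %.3g] y [%.3g, %.3g]\n",
              nrow(x), min(x[, 1]), max(x[, 1]), min(x[, 2]), max(x[, 2])))
  invisible(x)
}

#' Parametric description of a synthetic circle or ellipse
#'
#' A `shape_spec` records the geometry of one synthetic test shape: the
#' semi-axes `a >= b`, the radius `r` of the circle with the same area
#' (`pi * a * b == pi * r^2`), the axis ratio `q = b / a`, and the number of
#' boundary samples used to realize the shape as a polygon.
#'
#' @param kind `"circle"` or `"ellipse"`.
#' @param reference_radius Radius (px) of the same-area circle.
#' @param axis_ratio Minor/major axis ratio in `(0, 1]`; 1 for circles.
#' @param n_samples Number of boundary vertices (default 300).
#' @param center Shape center `(x, y)` in px.
#' @return A list of class `"shape_spec"`.
#' @export
shape_spec <- function(kind = c("circle", "ellipse"), reference_radius,
                       axis_ratio = 1, n_samples = 300L, center = c(0, 0)) {
  kind <- match.arg(kind)
  if (!is.numeric(reference_radius) || length(reference_radius) != 1L ||
      reference_radius <= 0)
    stop("reference_radius must be a single positive number")
  if (!is.numeric(axis_ratio) || length(axis_ratio) != 1L ||
      axis_ratio <= 0 || axis_ratio > 1)
    stop("axis_ratio must be in (0, 1]")
  if (kind == "circle" && axis_ratio != 1)
    stop("a circle has axis_ratio 1")
  if (n_samples < 3L) stop("n_samples must be at least 3")
  a <- reference_radius / sqrt(axis_ratio)
  b <- reference_radius * sqrt(axis_ratio)
  stopifnot(abs(a * b - reference_radius^2) <= 1e-9 * reference_radius^2)
  structure(list(kind = kind, semi_major = a, semi_minor = b,
                 reference_radius = reference_radius, axis_ratio = axis_ratio,
                 n_samples = as.integer(n_samples), center = as.numeric(center)),
            class = "shape_spec")
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf("<shape_spec> %s  a = %.4g  b = %.4g  (same-area r = %.4g, q = %.2g, %d samples)\n",
              x$kind, x$semi_major, x$semi_minor, x$reference_radius,
              x$axis_ratio, x$n_samples))
  invisible(x)
}

#' Realize a shape_spec as a sub-pixel contour
#'
#' Samples `x = a cos(t)`, `y = b sin(t)` at `n_samples` uniformly spaced
#' parameter values `t = 2*pi*k/n`, `k = 0 .. n-1` (endpoint excluded so no
#' vertex is duplicated).
#'
#' @param spec A [shape_spec()].
#' @return A [as_contour()] matrix with `spec$n_samples` vertices.
#' @export
contour_from_spec <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  t <- (seq_len(spec$n_samples) - 1) * 2 * pi / spec$n_samples
  as_contour(cbind(spec$center[1] + spec$semi_major * cos(t),
                   spec$center[2] + spec$semi_minor * sin(t)))
}

#' Sub-pixel circle contour
#'
#' @param radius Circle radius in px (> 0).
#' @param n_samples Number of boundary vertices (>= 3, default 300).
#' @param center Center `(x, y)` in px.
#' @return A `"faz_contour"` with `n_samples` vertices, each at distance
#'   `radius` from `center`.
#' @examples
#' p <- make_circle(10)
#' range(sqrt(rowSums(p^2)))  # all 10
#' @export
make_circle <- function(radius, n_samples = 300L, center = c(0, 0)) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a single positive number")
  if (n_samples < 3L) stop("n_samples must be at least 3")
  contour_from_spec(shape_spec("circle", reference_radius = radius,
                               n_samples = n_samples, center = center))
}

#' Same-area ellipses at given axis ratios
#'
#' For each ratio `q` builds the ellipse with semi-axes `a = r / sqrt(q)`,
#' `b = r * sqrt(q)` so that `pi * a * b = pi * r^2` (same area as the
#' reference circle).
#'
#' @param reference_radius Radius of the same-area circle (px).
#' @param ratios Axis ratios in `(0, 1]`; defaults to the 10:4, 10:6, 10:8
#'   aspect ratios.
#' @param n_samples Vertices per contour.
#' @param center Common center.
#' @return A named list of `"faz_contour"` objects (names are the ratios).
#' @export
make_same_area_ellipses <- function(reference_radius, ratios = c(0.4, 0.6, 0.8),
                                    n_samples = 300L, center = c(0, 0)) {
  if (any(ratios <= 0 | ratios > 1))
    stop("every axis ratio must be in (0, 1]")
  out <- lapply(ratios, function(q)
    contour_from_spec(shape_spec(if (q == 1) "circle" else "ellipse",
                                 reference_radius = reference_radius,
                                 axis_ratio = q, n_samples = n_samples,
                                 center = center)))
  names(out) <- format(ratios)
  out
}

#' FAZ-like irregular blob contour
#'
#' Generates a simply connected, smoothly irregular closed contour emulating a
#' segmented foveal avascular zone: a radial Fourier perturbation of a circle,
#' `r(theta) = r0 * (1 + sum_k a_k cos(k theta + phi_k))` for
#' `k = 2 .. n_harmonics`, with amplitudes drawn uniformly in
#' `[-irregularity/k, irregularity/k]`. The `1/k` spectral decay keeps the
#' border smooth; `irregularity < 0.5` guarantees a simple (star-shaped) curve.
#'
#' @param seed Integer seed; the same seed always returns the same contour.
#' @param mean_radius Base radius `r0` in px (> 2).
#' @param irregularity Total perturbation scale in `[0, 0.5)`.
#' @param n_harmonics Highest harmonic (k runs from 2).
#' @param n_samples Number of boundary vertices.
#' @param center Center `(x, y)`.
#' @return A `"faz_contour"`.
#' @export
make_faz_blob <- function(seed, mean_radius = 35, irregularity = 0.2,
                          n_harmonics = 8L, n_samples = 300L, center = c(0, 0)) {
  if (mean_radius <= 2) stop("mean_radius must exceed 2 px")
  if (irregularity < 0 || irregularity >= 0.5)
    stop("irregularity must be in [0, 0.5) to avoid self-intersection")
  if (n_harmonics < 2L) stop("n_harmonics must be at least 2")
  k <- 2:n_harmonics
  draws <- local_rng(seed, stats::runif(2L * length(k)))
  amp <- (2 * draws[seq_along(k)] - 1) * irregularity / k
  phi <- draws[length(k) + seq_along(k)] * 2 * pi
  theta <- (seq_len(n_samples) - 1) * 2 * pi / n_samples
  pert <- rep(0, n_samples)
  for (i in seq_along(k)) pert <- pert + amp[i] * cos(k[i] * theta + phi[i])
  r <- mean_radius * (1 + pert)
  as_contour(cbind(center[1] + r * cos(theta), center[2] + r * sin(theta)))
}

# Run `expr` under a private RNG stream without disturbing the caller's
# .Random.seed.
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read / write contour CSV files
#'
#' Contour files have a header row `x,y` and one sub-pixel vertex per line.
#'
#' @param path File path.
#' @return `read_contour_csv()` returns a `"faz_contour"`.
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("contour CSV must have columns 'x' and 'y'")
  as_contour(cbind(df$x, df$y))
}

#' @rdname read_contour_csv
#' @param contour A contour to write.
#' @export
write_contour_csv <- function(contour, path) {
  contour <- as_contour(contour)
  utils::write.csv(data.frame(x = contour[, 1], y = contour[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}
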