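#' Foreground pixel count
#'
#' Pixel-domain area estimator used identically by both software conventions:
#' the number of foreground pixels. Holes (if any) are not counted.
#'
#' @param mask A [faz_mask()].
#' @return Area in px^2.
#' @export
region_area <- function(mask) {
  stopifnot(inherits(mask, "faz_mask"))
  n <- sum(mask$grid)
  if (n == 0L) stop("mask has no foreground pixels")
  n
}

# Moore neighbourhood in clockwise screen order (y down), starting West.
# Columns: drow, dcol.
.moore <- matrix(c(0L, -1L,   # W
                   -1L, -1L,  # NW
                   -1L, 0L,   # N
                   -1L, 1L,   # NE
                   0L, 1L,    # E
                   1L, 1L,    # SE
                   1L, 0L,    # S
                   1L, -1L),  # SW
                 ncol = 2L, byrow = TRUE)

#' Trace the outer boundary of a single region (Moore-neighbour tracing)
#'
#' Follows the 8-connected outer boundary clockwise (on screen, y down)
#' starting from the top-most then left-most foreground pixel, scanning the
#' Moore neighbourhood clockwise from the backtrack position. The returned
#' path is closed implicitly (first pixel not repeated) and may revisit
#' pixels on one-pixel-wide spurs (traversed out and back). Deterministic for
#' a given mask.
#'
#' @param mask A [faz_mask()] with exactly one foreground component.
#' @return Integer matrix with columns `row`, `col` (grid indices).
#' @export
trace_boundary <- function(mask) {
  assert_single_region(mask)
  g <- mask$grid
  nr <- nrow(g); nc <- ncol(g)
  fg <- which(g == 1L, arr.ind = TRUE)
  r0 <- min(fg[, 1])
  c0 <- min(fg[fg[, 1] == r0, 2])
  is_fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && g[r, c] == 1L
  # one tracing step: from state (cur, back) find the next boundary pixel by
  # scanning the Moore ring clockwise starting just past the backtrack
  step <- function(cur, back) {
    off <- back - cur
    k0 <- which(.moore[, 1] == off[1] & .moore[, 2] == off[2])
    for (s in 1:8) {
      k <- ((k0 - 1L + s) %% 8L) + 1L
      cand <- cur + .moore[k, ]
      if (is_fg(cand[1], cand[2])) {
        prevk <- ((k0 - 1L + s - 1L) %% 8L) + 1L
        return(list(cur = cand, back = cur + .moore[prevk, ]))
      }
    }
    NULL
  }
  # backtrack starts at the West neighbour of the start pixel (background,
  # since the start is the left-most pixel of the top row)
  start <- c(r0, c0)
  first <- step(start, c(r0, c0 - 1L))
  if (is.null(first)) {
    out <- matrix(start, 1L, 2L); colnames(out) <- c("row", "col")
    return(out)
  }
  # walk until the state right after the start pixel recurs (the tracing
  # step is deterministic, so this closes exactly one full boundary cycle)
  path <- matrix(0L, 8L * (nr * nc) + 8L, 2L)
  path[1L, ] <- start; np <- 1L
  state <- first
  repeat {
    np <- np + 1L
    if (np > nrow(path)) stop("boundary trace did not terminate")
    path[np, ] <- state$cur
    state <- step(state$cur, state$back)
    if (identical(state$cur, first$cur) && identical(state$back, first$back))
      break
  }
  # the cycle re-enters through the start pixel; drop the duplicate
  if (np > 1L && all(path[np, ] == start)) np <- np - 1L
  out <- path[seq_len(np), , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

# Chain-code statistics of a closed boundary path: counts of axial and
# diagonal steps and of direction changes (corners), cyclically.
chain_stats <- function(path) {
  n <- nrow(path)
  if (n < 2L) return(list(n_axial = 0L, n_diag = 0L, n_corner = 0L))
  nxt <- path[c(2:n, 1L), , drop = FALSE]
  d <- nxt - path
  diag <- d[, 1] != 0L & d[, 2] != 0L
  code <- d[, 1] * 3L + d[, 2]  # unique per direction
  turns <- sum(code != code[c(n, seq_len(n - 1L))])
  list(n_axial = sum(!diag), n_diag = sum(diag), n_corner = as.integer(turns))
}

#' Chain-code perimeter (length of the traced boundary path)
#'
#' Sums 1 for axial and `sqrt(2)` for diagonal steps along the closed
#' boundary path: the historical regionprops-style perimeter. Systematically
#' biased high on smooth shapes (diagonal-heavy boundaries).
#'
#' @param mask A [faz_mask()] with a single foreground component.
#' @return Perimeter in px; 0 for a single-pixel region.
#' @export
perimeter_chain8 <- function(mask) {
  s <- chain_stats(trace_boundary(mask))
  s$n_axial + sqrt(2) * s$n_diag
}

#' Corner-weighted chain-code perimeter
#'
#' The corner-count-corrected boundary-path estimator
#' `P = w_a * N_axial + w_d * N_diag + w_c * N_corner`
#' with the Vossepoel-Smeulders weights `(0.980, 1.406, -0.091)` by default
#' (the modern regionprops-style perimeter, near-unbiased on smooth shapes).
#' `N_corner` counts direction changes along the closed path.
#'
#' @param mask A [faz_mask()] with a single foreground component.
#' @param weights Numeric triple `(axial, diagonal, corner)`.
#' @return Perimeter in px.
#' @export
perimeter_corner_weighted <- function(mask,
                                      weights = c(0.980, 1.406, -0.091)) {
  stopifnot(length(weights) == 3L)
  s <- chain_stats(trace_boundary(mask))
  weights[1] * s$n_axial + weights[2] * s$n_diag + weights[3] * s$n_corner
}

#' Crack-boundary outline of a single region
#'
#' Walks the outer outline along pixel edges (the "crack" between foreground
#' and background), clockwise on screen with the foreground kept on the
#' right, starting at the top-left corner of the top-most/left-most
#' foreground pixel. Diagonal contacts are kept separated (4-connected
#' cracks). Returns the polygon of outline corners in contour coordinates,
#' with collinear runs merged.
#'
#' @param mask A [faz_mask()] with a single foreground component.
#' @return List with `vertices` (two-column x, y matrix of corner points, in
#'   contour coordinates, pixel corners at half-integers), `n_edges` (total
#'   unit crack edges) and `run_lengths` (edge count of each polygon side).
#' @export
crack_polygon <- function(mask) {
  assert_single_region(mask)
  g <- mask$grid
  nr <- nrow(g); nc <- ncol(g)
  fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && g[r, c] == 1L
  idx <- which(g == 1L, arr.ind = TRUE)
  r0 <- min(idx[, 1]); c0 <- min(idx[idx[, 1] == r0, 2])
  # corner (i, j) = top-left corner of pixel (i, j)
  # directions: 1 E, 2 S, 3 W, 4 N as (drow, dcol) of corner movement
  dd <- matrix(c(0L, 1L, 1L, 0L, 0L, -1L, -1L, 0L), ncol = 2L, byrow = TRUE)
  # pixel on the right of an edge leaving corner (i, j) in direction d
  pright <- function(i, j, d) switch(d, c(i, j), c(i, j - 1L), c(i - 1L, j - 1L), c(i - 1L, j))
  start <- c(r0, c0); dstart <- 1L
  cur <- start; d <- dstart
  max_edges <- 4L * nr * nc + 16L
  corners <- matrix(0L, max_edges, 2L)
  ncorn <- 0L; n_edges <- 0L
  runs <- integer(0); runlen <- 0L
  repeat {
    nxt <- cur + dd[d, ]
    n_edges <- n_edges + 1L; runlen <- runlen + 1L
    # choose direction out of nxt: prefer left turn, then straight, then right
    dl <- ((d - 2L) %% 4L) + 1L  # left of d (counter-clockwise)
    ds <- d
    dr <- (d %% 4L) + 1L
    newd <- NA_integer_
    for (cand in c(dl, ds, dr)) {
      pr <- pright(nxt[1], nxt[2], cand)
      if (fg(pr[1], pr[2])) { newd <- cand; break }
    }
    if (is.na(newd)) stop("crack walk lost the boundary")  # cannot happen
    if (newd != d) {
      ncorn <- ncorn + 1L
      corners[ncorn, ] <- nxt
      runs <- c(runs, runlen)
      runlen <- 0L
    }
    cur <- nxt; d <- newd
    if (all(cur == start) && d == dstart) break
    if (n_edges > max_edges) stop("crack walk did not terminate")
  }
  # edges walked after the last corner belong to the side that closes on the
  # first recorded corner
  if (runlen > 0L && length(runs)) runs[1] <- runs[1] + runlen
  v <- corners[seq_len(ncorn), , drop = FALSE]
  xy <- cbind(x = mask$origin[1] + v[, 2] - 1 - 0.5,
              y = mask$origin[2] + v[, 1] - 1 - 0.5)
  list(vertices = xy, n_edges = n_edges, run_lengths = runs)
}

#' Traced-outline perimeter (particle-analysis style)
#'
#' Perimeter of the crack-boundary outline with the particle-analysis
#' corner-counting correction: with the outline decomposed into axis-aligned
#' sides, `P = w_e * (total edge length) + w_c * n_corners`, where corners
#' between two unit-length sides are counted alternately (a run of unit
#' staircase steps counts every other corner, approximating the staircase by
#' diagonal moves). Default weights `w_e = 0.948` and
#' `w_c = 1.340 - 2 * 0.948` make the estimator near-unbiased on smooth
#' shapes: each counted staircase corner converts two weighted unit edges
#' into one diagonal step of length `1.340 = 0.948 * sqrt(2)`.
#'
#' @param mask A [faz_mask()] with a single foreground component.
#' @param edge_weight Weight per unit crack edge.
#' @param corner_weight Additive weight per counted corner.
#' @param style `"imagej"` for the alternating corner count described above,
#'   or `"corner_deficit"` for the plain crack length minus
#'   `(2 - sqrt(2))` per convex corner.
#' @return Perimeter in px.
#' @export
perimeter_traced <- function(mask, edge_weight = 0.948,
                             corner_weight = 1.340 - 2 * 0.948,
                             style = c("imagej", "corner_deficit")) {
  style <- match.arg(style)
  cp <- crack_polygon(mask)
  sides <- cp$run_lengths
  n <- length(sides)
  if (n == 0L) {  # straight loop cannot happen; single pixel gives 4 sides
    return(edge_weight * cp$n_edges)
  }
  if (style == "imagej") {
    # alternate corner counting over unit-unit corners; sides longer than one
    # edge always count their corner
    side_prev <- sides[n]
    corner <- FALSE
    ncorners <- 0L
    for (i in seq_len(n)) {
      if (side_prev > 1L || !corner) {
        corner <- TRUE
        ncorners <- ncorners + 1L
      } else corner <- FALSE
      side_prev <- sides[i]
    }
    edge_weight * cp$n_edges + corner_weight * ncorners
  } else {
    # convex corners = left turns of the clockwise walk; for a simply
    # connected region convex - concave = 4
    turn <- turn_signs(cp$vertices)
    n_convex <- sum(turn > 0)
    cp$n_edges - (2 - sqrt(2)) * n_convex
  }
}

# Signed turn at each vertex of a closed polygon (positive = convex for a
# clockwise walk in screen coordinates, y down).
turn_signs <- function(v) {
  n <- nrow(v)
  a <- v[c(n, seq_len(n - 1L)), , drop = FALSE]
  b <- v
  cc <- v[c(2:n, 1L), , drop = FALSE]
  e1 <- b - a; e2 <- cc - b
  # cross product z; with y down, clockwise convex turns have positive z
  sign(e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Moment-based best-fit ellipse of a binary region
#'
#' Fits an ellipse by the second central moments of the foreground pixel
#' centers, with the `+ 1/12` pixel-extent correction added to both diagonal
#' moments (the variance of a unit pixel). Under the `"moment_normalized"`
#' convention the full axes are `4 * sqrt(eigenvalue)` (an ideal ellipse
#' recovers its axes exactly). Under `"equal_area"` the axes are rescaled so
#' the fitted ellipse has exactly the region's pixel-count area; the axis
#' ratio, hence AR roundness, is identical between conventions.
#'
#' @param mask A [faz_mask()] with at least two foreground pixels.
#' @param convention `"moment_normalized"` or `"equal_area"`.
#' @return A list of class `"ellipse_fit"` with `major_axis`, `minor_axis`
#'   (full lengths, px), `orientation` (radians) and `convention`.
#' @export
fit_ellipse_moments <- function(mask,
                                convention = c("moment_normalized", "equal_area")) {
  convention <- match.arg(convention)
  stopifnot(inherits(mask, "faz_mask"))
  idx <- which(mask$grid == 1L, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 2L) stop("ellipse fit needs at least 2 foreground pixels")
  x <- idx[, 2]; y <- idx[, 1]
  mx <- mean(x); my <- mean(y)
  uxx <- mean((x - mx)^2) + 1 / 12
  uyy <- mean((y - my)^2) + 1 / 12
  uxy <- mean((x - mx) * (y - my))
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  l1 <- (uxx + uyy + common) / 2
  l2 <- (uxx + uyy - common) / 2
  if (l2 <= 0) stop("degenerate region: zero variance along one axis")
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  if (convention == "equal_area") {
    s <- sqrt(n / (pi * (major / 2) * (minor / 2)))
    major <- major * s
    minor <- minor * s
  }
  orientation <- if (uxy == 0) {
    if (uxx >= uyy) 0 else pi / 2
  } else atan2(2 * uxy, uxx - uyy) / 2
  structure(list(major_axis = major, minor_axis = minor,
                 orientation = orientation, convention = convention),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit %s> major %.4g px, minor %.4g px, orientation %.3f rad\n",
              x$convention, x$major_axis, x$minor_axis, x$orientation))
  invisible(x)
}

#' Aspect-ratio (AR) roundness
#'
#' `minor_axis / major_axis` of the best-fit ellipse, equivalently
#' `4 * Area / (pi * MajorAxis^2)` for an exact ellipse. Identical across the
#' two ellipse-fit normalizations. Approaches 1 for a circle.
#'
#' @param fit An `"ellipse_fit"` (from [fit_ellipse_moments()]) or a
#'   [faz_mask()] (fitted on the fly).
#' @return Roundness in (0, 1].
#' @export
ar_roundness <- function(fit) {
  if (inherits(fit, "faz_mask")) fit <- fit_ellipse_moments(fit)
  stopifnot(inherits(fit, "ellipse_fit"))
  fit$minor_axis / fit$major_axis
}

#' Software-convention circularity of a mask
#'
#' `4 pi A / P^2` with `A` the pixel count and `P` the convention's perimeter
#' estimator. The regionprops-style (`"matlab_style"`) convention uses the
#' corner-weighted perimeter and optionally the small-region correction
#' factor `(1 - 0.5/rho)^2` with `rho = P/(2 pi) + 0.5`; uncorrected values
#' may exceed 1 on tiny regions. The particle-analysis-style
#' (`"imagej_style"`) convention uses, by default, the chain-code boundary
#' perimeter (which overestimates smooth outlines by about 5.5 %, so a large
#' rasterized circle reports circularity near 0.9 — the documented behaviour
#' of particle analysis, whose Perimeter column and circularity denominator
#' use different estimators) and caps the result at 1.0.
#'
#' @param mask A [faz_mask()] with a single foreground component.
#' @param convention `"matlab_style"` or `"imagej_style"`.
#' @param apply_small_region_correction Apply the matlab-style correction
#'   factor (ignored for imagej_style); defaults to the option set.
#' @param options Algorithm constants, see [faz_options()].
#' @return Dimensionless circularity.
#' @export
software_circularity <- function(mask,
                                 convention = c("matlab_style", "imagej_style"),
                                 apply_small_region_correction = NULL,
                                 options = faz_options()) {
  convention <- match.arg(convention)
  a <- region_area(mask)
  if (convention == "matlab_style") {
    if (is.null(apply_small_region_correction))
      apply_small_region_correction <- options$circularity_correction
    p <- perimeter_corner_weighted(mask, weights = options$chain_weights)
    circ <- 4 * pi * a / p^2
    if (apply_small_region_correction) {
      rho <- p / (2 * pi) + 0.5
      circ <- circ * (1 - 0.5 / rho)^2
    }
    circ
  } else {
    p <- if (identical(options$imagej_circ_perimeter, "traced"))
      perimeter_traced(mask, edge_weight = options$traced_edge_weight,
                       corner_weight = options$traced_corner_weight,
                       style = options$traced_style)
    else perimeter_chain8(mask)
    circ <- 4 * pi * a / p^2
    if (isTRUE(options$imagej_circ_cap)) circ <- min(1.0, circ)
    circ
  }
}
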