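#' Circle fits
#'
#' @param center `(x, y)` center in px.
#' @param radius Radius in px (>= 0).
#' @param role `"inscribed"` or `"circumscribed"`.
#' @return A list of class `"circle_fit"`.
#' @export
circle_fit <- function(center, radius, role = c("inscribed", "circumscribed")) {
  role <- match.arg(role)
  if (radius < 0) stop("radius must be non-negative")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 role = role), class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit %s> center (%.4g, %.4g), radius %.6g px\n",
              x$role, x$center[1], x$center[2], x$radius))
  invisible(x)
}

circle_from_2 <- function(p, q) {
  c((p + q) / 2, sqrt(sum((p - q)^2)) / 2)
}

# circumcircle through three points; NULL if collinear
circle_from_3 <- function(a, b, cc) {
  ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- cc[1]; cy <- cc[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14 * (abs(ax) + abs(bx) + abs(cx) + 1)) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
}

in_circle <- function(circ, p, tol = 1e-9) {
  sqrt((p[1] - circ[1])^2 + (p[2] - circ[2])^2) <= circ[3] * (1 + tol) + tol
}

#' Minimum circumscribed (smallest enclosing) circle
#'
#' Exact smallest enclosing circle of a point set by the randomized
#' incremental (Welzl-style) algorithm, after pruning to the convex hull.
#' The insertion order is shuffled under a fixed internal seed so the result
#' and runtime are deterministic. All points lie inside or on the returned
#' circle to 1e-9 relative tolerance; the circle is determined by at most
#' three support points.
#'
#' @param points Two-column matrix of `(x, y)` coordinates (>= 1 point).
#' @return A `"circle_fit"` with role `"circumscribed"`.
#' @export
min_circumscribed_circle <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points)) points <- matrix(points, ncol = 2L)
  if (nrow(points) < 1L) stop("need at least one point")
  storage.mode(points) <- "double"
  if (nrow(points) == 1L)
    return(circle_fit(points[1, ], 0, "circumscribed"))
  if (nrow(points) > 3L) {
    h <- grDevices::chull(points[, 1], points[, 2])
    points <- points[h, , drop = FALSE]
  }
  n <- nrow(points)
  if (n > 2L) {
    ord <- local_rng(780301L, sample.int(n))
    points <- points[ord, , drop = FALSE]
  }
  circ <- circle_from_2(points[1, ], points[2, ])
  if (n >= 3L) for (i in 3:n) {
    pi_ <- points[i, ]
    if (in_circle(circ, pi_)) next
    # smallest circle containing points[1..i] with pi_ on the boundary
    circ <- circle_from_2(points[1, ], pi_)
    for (j in seq_len(i - 1L)[-1]) {
      pj <- points[j, ]
      if (in_circle(circ, pj)) next
      circ <- circle_from_2(pi_, pj)
      for (k in seq_len(j - 1L)) {
        pk <- points[k, ]
        if (in_circle(circ, pk)) next
        c3 <- circle_from_3(pi_, pj, pk)
        if (!is.null(c3)) circ <- c3
        else {  # collinear: widest two-point circle
          cand <- list(circle_from_2(pi_, pk), circle_from_2(pj, pk),
                       circle_from_2(pi_, pj))
          circ <- cand[[which.max(vapply(cand, `[`, 0, 3L))]]
        }
      }
    }
  }
  circle_fit(circ[1:2], circ[3], "circumscribed")
}

# Minimum distance from point p to the closed polygon outline `v`
# (two-column vertex matrix); vectorized over edges.
dist_to_polygon <- function(p, v) {
  a <- v
  b <- v[c(2:nrow(v), 1L), , drop = FALSE]
  ab <- b - a
  ap <- cbind(p[1] - a[, 1], p[2] - a[, 2])
  len2 <- rowSums(ab^2)
  t <- pmin(1, pmax(0, ifelse(len2 > 0, (ap[, 1] * ab[, 1] + ap[, 2] * ab[, 2]) / len2, 0)))
  dx <- ap[, 1] - t * ab[, 1]
  dy <- ap[, 2] - t * ab[, 2]
  sqrt(min(dx^2 + dy^2))
}

#' Maximum inscribed circle of a mask
#'
#' Finds the foreground location with the greatest Euclidean distance to the
#' background via the exact distance transform, then (optionally) refines the
#' center to sub-pixel precision by direct maximization of the boundary
#' distance. Integer-grid ties are broken towards the smallest `(y, x)`.
#'
#' The `reference` argument selects which boundary representation distances
#' are measured against, matching the conventions of mask-consuming MIC
#' utilities:
#' \describe{
#'   \item{`"background_centers"`}{distance to the nearest background pixel
#'     center (the raw distance-transform value; the default). Note this is
#'     about half a pixel more generous than the polygon references, so on a
#'     rasterized circle the MIC radius can marginally exceed the
#'     boundary-center MCC radius.}
#'   \item{`"boundary_centers"`}{distance to the polygon through the traced
#'     boundary pixel centers (the representation used by contour-tracing
#'     MIC utilities).}
#'   \item{`"crack"`}{distance to the pixel-edge (crack) outline: pixels are
#'     treated as unit squares.}
#' }
#'
#' @param mask A [faz_mask()] with a single non-empty foreground component.
#' @param reference Boundary representation (see above).
#' @param refine Sub-pixel refinement of the center (Nelder-Mead ascent of
#'   the distance field, seeded at the distance-transform maximum with
#'   quadratic peak interpolation). If `FALSE`, the center stays on the
#'   integer grid.
#' @return A `"circle_fit"` with role `"inscribed"`, center in contour
#'   coordinates.
#' @export
max_inscribed_circle <- function(mask,
                                 reference = c("background_centers",
                                               "boundary_centers", "crack"),
                                 refine = TRUE) {
  reference <- match.arg(reference)
  assert_single_region(mask)
  d <- EBImage::distmap(mask$grid)
  dm <- max(d)
  # arg-max with deterministic tie-break: smallest row (y), then column (x)
  idx <- which(d == dm, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  r0 <- idx[1, 1]; c0 <- idx[1, 2]
  center <- c(c0, r0)  # (x, y) in grid units
  # quadratic peak interpolation on the distance field
  if (refine && r0 > 1 && r0 < nrow(d) && c0 > 1 && c0 < ncol(d)) {
    gx <- (d[r0, c0 + 1] - d[r0, c0 - 1]) / 2
    gy <- (d[r0 + 1, c0] - d[r0 - 1, c0]) / 2
    hxx <- d[r0, c0 + 1] - 2 * dm + d[r0, c0 - 1]
    hyy <- d[r0 + 1, c0] - 2 * dm + d[r0 - 1, c0]
    hxy <- (d[r0 + 1, c0 + 1] - d[r0 + 1, c0 - 1] -
            d[r0 - 1, c0 + 1] + d[r0 - 1, c0 - 1]) / 4
    det <- hxx * hyy - hxy^2
    if (is.finite(det) && det > 1e-12) {
      off <- -solve(matrix(c(hxx, hxy, hxy, hyy), 2), c(gx, gy))
      off <- pmax(-0.5, pmin(0.5, off))
      center <- center + off
    }
  }
  # distance function against the chosen boundary representation
  distfun <- switch(reference,
    boundary_centers = {
      bpath <- trace_boundary(mask)
      vg <- cbind(bpath[, 2], bpath[, 1])  # grid (x, y)
      function(p) dist_to_polygon(p, vg)
    },
    crack = {
      cp <- crack_polygon(mask)
      vg <- cbind(cp$vertices[, 1] - mask$origin[1] + 1,
                  cp$vertices[, 2] - mask$origin[2] + 1)
      function(p) dist_to_polygon(p, vg)
    },
    background_centers = {
      bg <- background_boundary_centers(mask)
      function(p) sqrt(min((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2))
    })
  if (refine) {
    opt <- stats::optim(center, function(p) -distfun(p), method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 400))
    if (-opt$value >= distfun(center)) center <- opt$par
  }
  radius <- distfun(center)
  circle_fit(c(mask$origin[1] + center[1] - 1, mask$origin[2] + center[2] - 1),
             radius, "inscribed")
}

# centers (grid x, y) of background pixels 4-adjacent to the foreground,
# including an implicit background frame around the grid
background_boundary_centers <- function(mask) {
  g <- mask$grid
  nr <- nrow(g); nc <- ncol(g)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- g
  nb <- pad[1:nr, 2:(nc + 1)] + pad[3:(nr + 2), 2:(nc + 1)] +
        pad[2:(nr + 1), 1:nc] + pad[2:(nr + 1), 3:(nc + 2)]
  idx <- which(g == 0L & nb > 0L, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}

#' Minimum circumscribed circle of a mask
#'
#' Smallest enclosing circle of the mask's boundary, under a selectable
#' boundary representation: the boundary pixel centers (default), the pixel
#' corners (pixels treated as unit squares), or a supplied sub-pixel contour.
#'
#' @param mask A [faz_mask()].
#' @param reference `"boundary_centers"`, `"pixel_corners"` or `"contour"`.
#' @param contour Required when `reference = "contour"`.
#' @return A `"circle_fit"` with role `"circumscribed"`, center in contour
#'   coordinates.
#' @export
min_circumscribed_circle_mask <- function(mask,
                                          reference = c("boundary_centers",
                                                        "pixel_corners",
                                                        "contour"),
                                          contour = NULL) {
  reference <- match.arg(reference)
  if (reference == "contour") {
    if (is.null(contour)) stop("contour reference requires a contour")
    return(min_circumscribed_circle(as_contour(contour)))
  }
  assert_single_region(mask)
  idx <- which(mask$grid == 1L, arr.ind = TRUE)
  pts <- cbind(mask$origin[1] + idx[, 2] - 1, mask$origin[2] + idx[, 1] - 1)
  h <- if (nrow(pts) > 3L) pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE] else pts
  if (reference == "pixel_corners") {
    # hull of all pixel corners = hull of (hull centers + the 4 corner offsets)
    h <- rbind(cbind(h[, 1] - 0.5, h[, 2] - 0.5), cbind(h[, 1] + 0.5, h[, 2] - 0.5),
               cbind(h[, 1] - 0.5, h[, 2] + 0.5), cbind(h[, 1] + 0.5, h[, 2] + 0.5))
  }
  min_circumscribed_circle(h)
}

#' Maximum inscribed circle of a sub-pixel contour
#'
#' Direct maximization of the distance to the polygon outline over the
#' interior, seeded by a coarse grid search. Intended for ideal-geometry
#' cross-checks of the mask-based solver.
#'
#' @param contour A simple closed [as_contour()].
#' @param grid_n Coarse search grid resolution per axis.
#' @return A `"circle_fit"` with role `"inscribed"`.
#' @export
max_inscribed_circle_contour <- function(contour, grid_n = 25L) {
  p <- as_contour(contour)
  xs <- seq(min(p[, 1]), max(p[, 1]), length.out = grid_n)
  ys <- seq(min(p[, 2]), max(p[, 2]), length.out = grid_n)
  cand <- as.matrix(expand.grid(x = xs, y = ys))
  inside <- points_in_polygon(cand, p)
  cand <- cand[inside, , drop = FALSE]
  if (nrow(cand) == 0L) cand <- matrix(colMeans(p), 1L)
  d0 <- apply(cand, 1L, dist_to_polygon, v = p)
  start <- cand[which.max(d0), ]
  opt <- stats::optim(start, function(q) -dist_to_polygon(q, p),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 1000))
  circle_fit(opt$par, -opt$value, "inscribed")
}

# even-odd point-in-polygon, vectorized over points
points_in_polygon <- function(pts, poly) {
  xa <- poly[, 1]; ya <- poly[, 2]
  xb <- c(xa[-1], xa[1]); yb <- c(ya[-1], ya[1])
  vapply(seq_len(nrow(pts)), function(i) {
    x <- pts[i, 1]; y <- pts[i, 2]
    cross <- (ya <= y & yb > y) | (yb <= y & ya > y)
    if (!any(cross)) return(FALSE)
    xc <- xa[cross] + (y - ya[cross]) * (xb[cross] - xa[cross]) / (yb[cross] - ya[cross])
    sum(xc < x) %% 2L == 1L
  }, logical(1))
}

#' MIC/MCC roundness
#'
#' Ratio of the area of the maximum inscribed circle to the area of the
#' minimum circumscribed circle, `(r_mic / r_mcc)^2`. Equals 1 for an ideal
#' circle and `q^2` for an ideal ellipse with axis ratio `q`.
#'
#' @param mic An inscribed `"circle_fit"`.
#' @param mcc A circumscribed `"circle_fit"` with positive radius.
#' @return Dimensionless roundness.
#' @export
mic_mcc_roundness <- function(mic, mcc) {
  stopifnot(inherits(mic, "circle_fit"), inherits(mcc, "circle_fit"))
  if (mic$role != "inscribed" || mcc$role != "circumscribed")
    stop("mic must be inscribed and mcc circumscribed")
  if (mcc$radius <= 0) stop("circumscribed radius must be positive")
  (mic$radius / mcc$radius)^2
}
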