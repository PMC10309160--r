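# Shared fixtures. The full 148-shape battery is expensive (~1-2 min), so it
# is computed once per test run and memoized here for every test that needs
# battery-wide statistics.

.cache <- new.env(parent = emptyenv())

full_battery <- function() {
  if (is.null(.cache$battery)) .cache$battery <- run_battery()
  .cache$battery
}

# small mask helpers --------------------------------------------------------

block_mask <- function(nr, nc, pad = 1L) {
  g <- matrix(0L, nr + 2L * pad, nc + 2L * pad)
  g[pad + seq_len(nr), pad + seq_len(nc)] <- 1L
  faz_mask(g)
}

# Independent O(n^3) smallest-enclosing-circle oracle: enumerate all point
# pairs (diameter circles) and triples (circumcircles), keep candidates that
# contain every point, return the smallest.
brute_force_mec <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  best <- c(NA, NA, Inf)
  contains_all <- function(cx, cy, r) {
    all(sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2) <= r + tol * (r + 1))
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    cx <- (pts[i, 1] + pts[j, 1]) / 2
    cy <- (pts[i, 2] + pts[j, 2]) / 2
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
    if (r < best[3] && contains_all(cx, cy, r)) best <- c(cx, cy, r)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (!(i < j && j < k)) next
    a <- pts[i, ]; b <- pts[j, ]; cc <- pts[k, ]
    d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) + cc[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) next
    ux <- ((sum(a^2)) * (b[2] - cc[2]) + (sum(b^2)) * (cc[2] - a[2]) +
           (sum(cc^2)) * (a[2] - b[2])) / d
    uy <- ((sum(a^2)) * (cc[1] - b[1]) + (sum(b^2)) * (a[1] - cc[1]) +
           (sum(cc^2)) * (b[1] - a[1])) / d
    r <- sqrt((a[1] - ux)^2 + (a[2] - uy)^2)
    if (r < best[3] && contains_all(ux, uy, r)) best <- c(ux, uy, r)
  }
  best
}

# closed-form perimeter approximation for an ellipse (Ramanujan II), used as
# an independent cross-check of the quadrature arc length
ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}
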