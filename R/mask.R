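#' Binary masks
#'
#' A `faz_mask` wraps an integer 0/1 matrix (`grid`, rows = y, columns = x)
#' together with `origin`, the contour-space `(x, y)` coordinate of the center
#' of pixel `grid[1, 1]`. Pixel `grid[i, j]` has center
#' `(origin[1] + j - 1, origin[2] + i - 1)`; conversions between contour and
#' grid coordinates always go through `origin`.
#'
#' @param grid A 0/1 matrix (any numeric/logical; nonzero is foreground).
#' @param origin Contour-space center of pixel `[1, 1]`.
#' @return A list of class `"faz_mask"` with elements `grid` and `origin`.
#' @export
faz_mask <- function(grid, origin = c(1, 1)) {
  if (!is.matrix(grid)) stop("grid must be a matrix")
  g <- matrix(as.integer(grid != 0), nrow(grid), ncol(grid))
  structure(list(grid = g, origin = as.numeric(origin)), class = "faz_mask")
}

#' @export
print.faz_mask <- function(x, ...) {
  cat(sprintf("<faz_mask> %d x %d px, %d foreground, origin (%.2f, %.2f)\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid), x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
as.matrix.faz_mask <- function(x, ...) x$grid

# grid (row, col) -> contour (x, y)
grid_to_xy <- function(mask, row, col) {
  cbind(x = mask$origin[1] + col - 1, y = mask$origin[2] + row - 1)
}

#' Rasterize a sub-pixel contour to a binary mask
#'
#' A pixel is foreground iff its center lies inside the polygon under the
#' even-odd rule, implemented as a half-open scanline fill: an edge covers
#' scanlines `min(y) <= y < max(y)` and a crossing at x-coordinate `c` covers
#' pixel centers `x >= c` up to the next crossing. Points exactly on an edge
#' are therefore resolved deterministically (inside when approached from the
#' lower-left), a measure-zero case for trigonometric contours.
#'
#' @param contour A simple closed [as_contour()].
#' @param padding Background margin around the bounding box, in px.
#' @return A [faz_mask()] tightly bounding the shape plus `padding`.
#' @export
rasterize <- function(contour, padding = 2L) {
  p <- as_contour(contour)
  if (polygon_area(p) == 0) stop("degenerate contour encloses no area")
  x0 <- floor(min(p[, 1])) - padding
  y0 <- floor(min(p[, 2])) - padding
  w <- ceiling(max(p[, 1])) + padding - x0 + 1
  h <- ceiling(max(p[, 2])) + padding - y0 + 1
  xa <- p[, 1]; ya <- p[, 2]
  xb <- c(xa[-1], xa[1]); yb <- c(ya[-1], ya[1])
  keep <- ya != yb
  xa <- xa[keep]; xb <- xb[keep]; ya <- ya[keep]; yb <- yb[keep]
  ylo <- pmin(ya, yb); yhi <- pmax(ya, yb)
  # integer scanlines (pixel-center y values) crossed by each edge, half-open
  first <- ceiling(ylo); last <- ceiling(yhi) - 1
  ns <- pmax(last - first + 1, 0)
  edge <- rep.int(seq_along(xa), ns)
  ys <- unlist(lapply(seq_along(xa), function(i)
    if (ns[i] > 0) seq.int(first[i], last[i]) else integer(0)), use.names = FALSE)
  xs <- xa[edge] + (ys - ya[edge]) * (xb[edge] - xa[edge]) / (yb[edge] - ya[edge])
  grid <- matrix(0L, h, w)
  if (length(ys)) {
    o <- order(ys, xs)
    ys <- ys[o]; xs <- xs[o]
    runs <- split(xs, ys)
    for (yy in names(runs)) {
      cr <- runs[[yy]]
      stopifnot(length(cr) %% 2L == 0L)
      i <- as.integer(yy) - y0 + 1
      for (k in seq(1L, length(cr), by = 2L)) {
        j1 <- ceiling(cr[k]) - x0 + 1
        j2 <- ceiling(cr[k + 1]) - 1 - x0 + 1
        if (j2 >= j1) grid[i, j1:j2] <- 1L
      }
    }
  }
  if (sum(grid) == 0L) stop("contour rasterized to an empty mask")
  faz_mask(grid, origin = c(x0, y0))
}

#' Upsample a mask by integer pixel replication
#'
#' Nearest-neighbour replication: each pixel becomes a `factor x factor`
#' block, so the foreground count scales exactly by `factor^2` and all
#' lengths by `factor`. The origin is scaled so grid coordinates remain
#' consistent under the magnified pixel grid.
#'
#' @param mask A [faz_mask()].
#' @param factor Integer >= 1.
#' @return The upsampled [faz_mask()].
#' @export
upsample_mask <- function(mask, factor) {
  stopifnot(inherits(mask, "faz_mask"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  if (factor == 1L) return(mask)
  g <- mask$grid[rep(seq_len(nrow(mask$grid)), each = factor),
                 rep(seq_len(ncol(mask$grid)), each = factor)]
  faz_mask(g, origin = mask$origin * factor)
}

#' Read / write binary mask image files
#'
#' Masks are single-channel 8-bit PNG (or TIFF) files; any value above zero is
#' foreground. Multi-channel images are reduced by their first channel with a
#' warning. The writer emits 0/255 PNG (or TIFF via the tiff package).
#'
#' @param path Image file path (`.png`, `.tif`/`.tiff`).
#' @param origin Origin to attach to the mask read (default `c(1, 1)`).
#' @return `read_mask()` returns a [faz_mask()].
#' @export
read_mask <- function(path, origin = c(1, 1)) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF masks requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported mask format: .", ext))
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    if (nch > 1L && !all(img == img[, , rep(1L, nch)]))
      warning("multi-channel mask with differing channels: using the first")
    img <- img[, , 1]
  }
  faz_mask(img > 0, origin = origin)
}

#' @rdname read_mask
#' @param mask A [faz_mask()] to write.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "faz_mask"))
  ext <- tolower(tools::file_ext(path))
  img <- mask$grid * 1.0  # writePNG expects [0,1]; 1 -> 255 in 8-bit
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("writing TIFF masks requires the 'tiff' package")
      tiff::writeTIFF(img, path, bits.per.sample = 8L)
    },
    stop("unsupported mask format: .", ext))
  invisible(path)
}

# Number of connected components of the foreground (8-connectivity via
# EBImage::bwlabel, which treats diagonal neighbours as connected).
n_components <- function(mask) {
  max(EBImage::bwlabel(mask$grid))
}

assert_single_region <- function(mask) {
  if (sum(mask$grid) == 0L) stop("mask has no foreground pixels")
  nc <- n_components(mask)
  if (nc != 1L)
    stop("mask has ", nc, " foreground components; a single region is required ",
         "(pre-select the FAZ component)")
  invisible(mask)
}
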