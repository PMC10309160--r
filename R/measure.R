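#' Measure one shape under every algorithm
#'
#' Computes the full metric panel for a single shape: sub-pixel (exact
#' coordinate) area, perimeter and circularity; theoretical values when the
#' shape is a parametric [shape_spec()]; pixel-domain area, the three
#' perimeter estimators, the two software-convention circularities, the
#' moment-fit ellipse axes and AR roundness; and MIC/MCC roundness from the
#' extremal-circle solvers.
#'
#' @param x A [shape_spec()], a list with elements `spec` and `contour`, a
#'   bare contour, or a [faz_mask()].
#' @param options Algorithm constants, see [faz_options()].
#' @param scale_mm_per_px Optional physical scale; when given, `area_mm2` and
#'   `perimeter_mm` columns are added (px values times scale^2 / scale).
#' @return A one-row `data.frame` with all metric columns.
#' @export
measure_shape <- function(x, options = faz_options(), scale_mm_per_px = NULL) {
  spec <- NULL; contour <- NULL; mask <- NULL
  if (inherits(x, "shape_spec")) {
    spec <- x; contour <- contour_from_spec(x)
  } else if (inherits(x, "faz_mask")) {
    mask <- x
  } else if (is.list(x) && !is.null(x$contour)) {
    spec <- x$spec; contour <- as_contour(x$contour)
  } else {
    contour <- as_contour(x)
  }
  if (is.null(mask)) mask <- rasterize(contour, padding = options$padding)
  if (is.null(contour)) {
    # real-mask path: the sub-pixel-style boundary is the crack outline
    contour <- as_contour(crack_polygon(mask)$vertices)
  }

  area_sub <- polygon_area(contour)
  perim_sub <- polygon_perimeter(contour)

  theo <- if (!is.null(spec)) theoretical_measures(spec) else
    list(area = NA_real_, perimeter = NA_real_)

  area_px <- region_area(mask)
  p_chain8 <- perimeter_chain8(mask)
  p_cw <- perimeter_corner_weighted(mask, weights = options$chain_weights)
  p_traced <- perimeter_traced(mask, edge_weight = options$traced_edge_weight,
                               corner_weight = options$traced_corner_weight,
                               style = options$traced_style)
  fit <- fit_ellipse_moments(mask, "moment_normalized")
  circ_ml <- software_circularity(mask, "matlab_style", options = options)
  circ_ij <- software_circularity(mask, "imagej_style", options = options)
  mic <- max_inscribed_circle(mask, reference = options$mic_reference,
                              refine = options$mic_refine)
  mcc <- min_circumscribed_circle_mask(mask, reference = options$mcc_reference,
                                       contour = contour)

  out <- data.frame(
    kind = if (!is.null(spec)) spec$kind else "mask",
    reference_radius = if (!is.null(spec)) spec$reference_radius else NA_real_,
    axis_ratio = if (!is.null(spec)) spec$axis_ratio else NA_real_,
    semi_major = if (!is.null(spec)) spec$semi_major else NA_real_,
    semi_minor = if (!is.null(spec)) spec$semi_minor else NA_real_,
    min_diameter_px = if (!is.null(spec)) 2 * spec$semi_minor else
      fit$minor_axis,
    theoretical_area = theo$area,
    theoretical_perimeter = theo$perimeter,
    area_subpixel = area_sub,
    perimeter_subpixel = perim_sub,
    circ_subpixel = circularity(area_sub, perim_sub, "standard"),
    circ_subpixel_iso = circularity(area_sub, perim_sub, "iso_sqrt"),
    area_px = area_px,
    perimeter_chain8 = p_chain8,
    perimeter_corner_weighted = p_cw,
    perimeter_traced = p_traced,
    circ_matlab_style = circ_ml,
    circ_imagej_style = circ_ij,
    major_axis = fit$major_axis,
    minor_axis = fit$minor_axis,
    ar_roundness = fit$minor_axis / fit$major_axis,
    mic_x = mic$center[1], mic_y = mic$center[2], mic_radius = mic$radius,
    mcc_x = mcc$center[1], mcc_y = mcc$center[2], mcc_radius = mcc$radius,
    mic_mcc_roundness = mic_mcc_roundness(mic, mcc),
    stringsAsFactors = FALSE)

  if (!is.null(scale_mm_per_px)) {
    if (scale_mm_per_px <= 0) stop("scale_mm_per_px must be positive")
    out$scale_mm_per_px <- scale_mm_per_px
    out$area_mm2 <- out$area_subpixel * scale_mm_per_px^2
    out$perimeter_mm <- out$perimeter_subpixel * scale_mm_per_px
  }
  out
}

#' Measure a user-supplied FAZ mask
#'
#' Entry point for real segmentation masks: verifies the mask holds a single
#' region, runs the full metric panel, and converts area/perimeter to
#' physical units. Sub-pixel-style measures are taken on the crack-edge
#' boundary outline of the mask.
#'
#' @param mask A [faz_mask()] (e.g. from [read_mask()]) with one region.
#' @param scale_mm_per_px Physical scale in mm per pixel (> 0); omit for
#'   pixel units only.
#' @param options See [faz_options()].
#' @return A one-row `data.frame` of metrics.
#' @export
measure_real_mask <- function(mask, scale_mm_per_px = NULL,
                              options = faz_options()) {
  stopifnot(inherits(mask, "faz_mask"))
  assert_single_region(mask)
  measure_shape(mask, options = options, scale_mm_per_px = scale_mm_per_px)
}
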