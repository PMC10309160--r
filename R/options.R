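#' Algorithm constants and conventions
#'
#' Bundles every tunable constant of the pixel-domain estimators so a run is
#' fully reproducible from its echoed configuration. Defaults are the
#' literature-standard values of the conventions each estimator replicates.
#'
#' @param chain_weights Corner-weighted perimeter weights
#'   `(axial, diagonal, corner)`; Vossepoel-Smeulders `(0.980, 1.406, -0.091)`.
#' @param traced_style Corner rule of the traced-outline perimeter,
#'   see [perimeter_traced()].
#' @param traced_edge_weight,traced_corner_weight Constants of the traced
#'   outline estimator.
#' @param circularity_correction Apply the regionprops-style small-region
#'   circularity correction (see [software_circularity()]). Off by default:
#'   the uncorrected convention is the one whose inter-software circularity
#'   relation is near-linear across shape sizes.
#' @param imagej_circ_perimeter Perimeter estimator inside the
#'   particle-analysis-style circularity: `"chain8"` (the boundary-path
#'   chain-code length, the convention that makes the circularity of a large
#'   rasterized circle come out near 0.9, as particle analysis is known to
#'   report) or `"traced"` (the corrected outline estimator that the
#'   Perimeter column itself uses).
#' @param imagej_circ_cap Cap particle-analysis-style circularity at 1.0.
#' @param mic_reference,mcc_reference Boundary representations for the
#'   extremal-circle solvers, see [max_inscribed_circle()] and
#'   [min_circumscribed_circle_mask()].
#' @param mic_refine Sub-pixel refinement of the MIC center.
#' @param padding Background margin when rasterizing contours, px.
#' @return A named list of class `"faz_options"`.
#' @export
faz_options <- function(chain_weights = c(0.980, 1.406, -0.091),
                        traced_style = "imagej",
                        traced_edge_weight = 0.948,
                        traced_corner_weight = 1.340 - 2 * 0.948,
                        circularity_correction = FALSE,
                        imagej_circ_perimeter = "chain8",
                        imagej_circ_cap = TRUE,
                        mic_reference = "background_centers",
                        mcc_reference = "boundary_centers",
                        mic_refine = TRUE,
                        padding = 2L) {
  structure(list(chain_weights = chain_weights,
                 traced_style = traced_style,
                 traced_edge_weight = traced_edge_weight,
                 traced_corner_weight = traced_corner_weight,
                 circularity_correction = circularity_correction,
                 imagej_circ_perimeter = imagej_circ_perimeter,
                 imagej_circ_cap = imagej_circ_cap,
                 mic_reference = mic_reference,
                 mcc_reference = mcc_reference,
                 mic_refine = mic_refine,
                 padding = as.integer(padding)),
            class = "faz_options")
}

#' @export
print.faz_options <- function(x, ...) {
  cat("<faz_options>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}
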