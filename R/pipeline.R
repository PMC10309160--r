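#' Radii of the synthetic shape battery
#'
#' The battery spans radii 2 to 1000 px. The individual radii are
#' logarithmically spaced (rounded to 4 significant figures): pixel-domain
#' metric bias is a function of shape size relative to the pixel, so log
#' spacing covers small shapes densely where the bias changes fastest.
#' Linear spacing is available for sensitivity checks.
#'
#' @param min,max Radius range in px (inclusive).
#' @param count Number of radii.
#' @param spacing `"log"` or `"linear"`.
#' @return Numeric vector of radii.
#' @export
battery_radii <- function(min = 2, max = 1000, count = 37L,
                          spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (count < 1L) stop("count must be at least 1")
  if (max < min) stop("max radius must be at least min radius")
  if (min < 1) stop("radii below 1 px are not rasterizable")
  r <- if (count == 1L) min else switch(spacing,
    log = exp(seq(log(min), log(max), length.out = count)),
    linear = seq(min, max, length.out = count))
  signif(r, 4)
}

#' Generate the synthetic circle/ellipse battery
#'
#' For every radius, one circle plus one same-area ellipse per axis ratio.
#' The default configuration (37 radii, ratios 0.4, 0.6, 0.8 corresponding to
#' aspect ratios 10:4, 10:6, 10:8, 300 boundary samples) yields 148 shapes.
#'
#' @param radii Radii of the reference circles (px), see [battery_radii()].
#' @param ratios Ellipse axis ratios in `(0, 1)`; may be empty.
#' @param n_samples Boundary vertices per shape.
#' @return A list of shapes, each a list with `spec` ([shape_spec()]) and
#'   `contour` ([as_contour()]).
#' @export
generate_battery <- function(radii = battery_radii(),
                             ratios = c(0.4, 0.6, 0.8),
                             n_samples = 300L) {
  if (any(ratios <= 0 | ratios > 1)) stop("axis ratios must be in (0, 1]")
  shapes <- list()
  for (r in radii) {
    qs <- c(1, ratios)
    for (q in qs) {
      spec <- shape_spec(if (q == 1) "circle" else "ellipse",
                         reference_radius = r, axis_ratio = q,
                         n_samples = n_samples)
      shapes[[length(shapes) + 1L]] <- list(spec = spec,
                                            contour = contour_from_spec(spec))
    }
  }
  shapes
}

#' Run the full metric panel over a shape battery
#'
#' Measures every shape with [measure_shape()] and returns one row per shape.
#' Deterministic: rerunning with the same configuration reproduces the table
#' exactly.
#'
#' @param radii,ratios,n_samples Battery configuration, see
#'   [generate_battery()].
#' @param shapes Alternatively, a ready-made battery list (overrides the
#'   configuration arguments).
#' @param options Algorithm constants, see [faz_options()].
#' @param verbose Print progress to stderr.
#' @return A `data.frame` of class `"faz_battery"` with one row per shape and
#'   the configuration attached as attribute `"config"`.
#' @export
run_battery <- function(radii = battery_radii(), ratios = c(0.4, 0.6, 0.8),
                        n_samples = 300L, shapes = NULL,
                        options = faz_options(), verbose = FALSE) {
  if (is.null(shapes)) shapes <- generate_battery(radii, ratios, n_samples)
  rows <- vector("list", length(shapes))
  for (i in seq_along(shapes)) {
    if (verbose) message(sprintf("shape %d/%d (r = %.4g, q = %.2g)",
                                 i, length(shapes),
                                 shapes[[i]]$spec$reference_radius,
                                 shapes[[i]]$spec$axis_ratio))
    rows[[i]] <- measure_shape(shapes[[i]], options = options)
  }
  out <- do.call(rbind, rows)
  out$shape_id <- seq_len(nrow(out))
  out <- out[, c("shape_id", setdiff(names(out), "shape_id"))]
  attr(out, "config") <- list(radii = radii, ratios = ratios,
                              n_samples = n_samples, options = options)
  class(out) <- c("faz_battery", class(out))
  out
}

#' @export
print.faz_battery <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<faz_battery> %d shapes (%d circles, %d ellipses)\n",
              nrow(x), sum(x$kind == "circle"), sum(x$kind == "ellipse")))
  if (!is.null(cfg))
    cat(sprintf("  radii %.4g .. %.4g px (%d), ratios %s, %d boundary samples\n",
                min(cfg$radii), max(cfg$radii), length(cfg$radii),
                paste(cfg$ratios, collapse = "/"), cfg$n_samples))
  cat("  columns: ", paste(utils::head(names(x), 12), collapse = ", "),
      ", ...\n", sep = "")
  invisible(x)
}

#' @export
summary.faz_battery <- function(object, ...) {
  out <- list(
    n = nrow(object),
    percent_differences = summarize_percent_differences(object),
    roundness_fit = relate_roundness(object),
    circularity_fit = relate_circularities(object),
    ar_exceeds = count_ar_exceeds_micmcc(object))
  class(out) <- "summary.faz_battery"
  out
}

#' @export
print.summary.faz_battery <- function(x, ...) {
  cat(sprintf("Battery of %d shapes\n\n", x$n))
  cat("Percent difference vs theoretical values:\n")
  print(x$percent_differences, digits = 4)
  cat("\nMIC/MCC roundness vs AR roundness:\n")
  print(x$roundness_fit)
  cat("\nParticle-analysis vs regionprops-style circularity:\n")
  print(x$circularity_fit)
  cat(sprintf("\nAR roundness > MIC/MCC roundness for %d of %d shapes\n",
              x$ar_exceeds["count"], x$ar_exceeds["total"]))
  invisible(x)
}

#' @export
plot.faz_battery <- function(x, ...) {
  graphics::plot(x$ar_roundness, x$mic_mcc_roundness, log = "xy",
                 xlab = "AR roundness", ylab = "MIC/MCC roundness",
                 pch = ifelse(x$kind == "circle", 1, 16), ...)
  graphics::abline(0, 1, lty = 2, untf = FALSE)
  fit <- relate_roundness(x)
  xs <- exp(seq(log(min(x$ar_roundness)), 0, length.out = 100))
  graphics::lines(xs, predict(fit, xs), col = 2)
  invisible(x)
}

#' Percent-difference summaries of each measurement method
#'
#' For each of the six methods (sub-pixel polygon area, pixel-count area,
#' sub-pixel coordinate perimeter, chain-code perimeter, corner-weighted
#' perimeter, traced-outline perimeter) summarizes the symmetric percent
#' difference against the theoretical value across shapes (min / mean / max),
#' and fits the ordinary least-squares line of theoretical (y) on measured
#' (x).
#'
#' @param battery A [run_battery()] table with theoretical values.
#' @return A `data.frame` with one row per method.
#' @export
summarize_percent_differences <- function(battery) {
  if (any(!is.finite(battery$theoretical_area)))
    stop("battery table lacks theoretical values")
  methods <- list(
    area_subpixel = c("theoretical_area", "area_subpixel"),
    area_pixel_count = c("theoretical_area", "area_px"),
    perimeter_subpixel = c("theoretical_perimeter", "perimeter_subpixel"),
    perimeter_chain8 = c("theoretical_perimeter", "perimeter_chain8"),
    perimeter_corner_weighted = c("theoretical_perimeter", "perimeter_corner_weighted"),
    perimeter_traced = c("theoretical_perimeter", "perimeter_traced"))
  rows <- lapply(names(methods), function(nm) {
    theo <- battery[[methods[[nm]][1]]]
    meas <- battery[[methods[[nm]][2]]]
    pd <- percent_difference(theo, meas)
    line <- stats::lm(theo ~ meas)
    data.frame(method = nm, min_pct = min(pd), mean_pct = mean(pd),
               max_pct = max(pd),
               linear_slope = unname(stats::coef(line)[2]),
               linear_intercept = unname(stats::coef(line)[1]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit a power law y = k * x^p
#'
#' Ordinary least squares of `log(y)` on `log(x)`; the goodness of fit is the
#' R-squared of that (linear, in log space) regression, alongside a
#' linear-space R-squared for transparency. Optionally filters out shapes
#' whose minimum diameter is below a threshold before fitting.
#'
#' @param x,y Positive vectors.
#' @param diameters Optional per-point minimum diameters (px) used with
#'   `min_diameter_px`.
#' @param min_diameter_px Exclude points with `diameters` below this value.
#' @return An object of class `"power_law_fit"` with coefficient `k`,
#'   exponent `p`, `r_squared` (log space), `r_squared_linear`, `n_points`
#'   and `fit_domain`.
#' @export
fit_power_law <- function(x, y, diameters = NULL, min_diameter_px = 0) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (any(x <= 0) || any(y <= 0)) stop("power-law fit requires positive values")
  keep <- if (!is.null(diameters) && min_diameter_px > 0)
    diameters >= min_diameter_px else rep(TRUE, length(x))
  if (sum(keep) < 3L)
    stop("fewer than 3 points remain after diameter filtering")
  xf <- x[keep]; yf <- y[keep]
  fit <- stats::lm(log(yf) ~ log(xf))
  k <- exp(unname(stats::coef(fit)[1]))
  p <- unname(stats::coef(fit)[2])
  # R-squared in log space, computed directly (summary.lm warns on exact fits)
  sst_log <- sum((log(yf) - mean(log(yf)))^2)
  r2 <- if (sst_log > 0) 1 - sum(stats::residuals(fit)^2) / sst_log else 1
  pred <- k * xf^p
  sse <- sum((yf - pred)^2)
  sst <- sum((yf - mean(yf))^2)
  structure(list(k = k, p = p, r_squared = r2,
                 r_squared_linear = if (sst > 0) 1 - sse / sst else NA_real_,
                 n_points = length(xf),
                 fit_domain = if (min_diameter_px > 0)
                   sprintf("min diameter >= %g px", min_diameter_px)
                 else "all shapes",
                 model = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, digits = 4, ...) {
  cat(sprintf("y = %.*g * x^%.*g   (R2 = %.*g, n = %d, %s)\n",
              digits, x$k, digits, x$p, digits, x$r_squared, x$n_points,
              x$fit_domain))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(k = object$k, p = object$p)
}

#' @export
predict.power_law_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(exp(stats::fitted(object$model)))
  object$k * newdata^object$p
}

#' @export
summary.power_law_fit <- function(object, ...) {
  cat("Power-law fit (least squares in log-log space)\n")
  print(object)
  cat(sprintf("linear-space R2 = %.4g\n", object$r_squared_linear))
  invisible(object)
}

#' @export
plot.power_law_fit <- function(x, ...) {
  m <- x$model
  xs <- exp(m$model[[2]]); ys <- exp(m$model[[1]])
  graphics::plot(xs, ys, log = "xy", xlab = "x", ylab = "y", ...)
  ord <- order(xs)
  graphics::lines(xs[ord], predict(x, xs[ord]), col = 2)
  invisible(x)
}

#' Power-law relation between MIC/MCC and AR roundness over a battery
#'
#' The default fit domain is the relation's validity domain (shapes at least
#' 6 px across): below that, pixel quantization of the inscribed and
#' circumscribed circles dominates both metrics. Set `min_diameter_px = 0`
#' for an include-all sensitivity fit.
#'
#' @param battery A [run_battery()] table.
#' @param min_diameter_px Minimum minor diameter for inclusion (0 = all).
#' @return A `"power_law_fit"` of MIC/MCC roundness on AR roundness.
#' @export
relate_roundness <- function(battery, min_diameter_px = 6) {
  fit_power_law(battery$ar_roundness, battery$mic_mcc_roundness,
                diameters = battery$min_diameter_px,
                min_diameter_px = min_diameter_px)
}

#' Power-law relation between the two software circularities
#'
#' Fits particle-analysis-style circularity as a power law of the
#' regionprops-style circularity across the battery. The default fit domain
#' is the relation's validity domain (shapes at least 16 px across): below
#' that the capped, quantized circularities decouple. Set
#' `min_diameter_px = 0` for an include-all sensitivity fit.
#'
#' @inheritParams relate_roundness
#' @return A `"power_law_fit"`.
#' @export
relate_circularities <- function(battery, min_diameter_px = 16) {
  fit_power_law(battery$circ_matlab_style, battery$circ_imagej_style,
                diameters = battery$min_diameter_px,
                min_diameter_px = min_diameter_px)
}

#' Count shapes whose AR roundness exceeds MIC/MCC roundness
#'
#' Strict inequality count over the battery table.
#'
#' @param battery A [run_battery()] table.
#' @return Named integer vector `c(count, total)`.
#' @export
count_ar_exceeds_micmcc <- function(battery) {
  c(count = sum(battery$ar_roundness > battery$mic_mcc_roundness),
    total = nrow(battery))
}

#' Write battery results and summary
#'
#' `write_battery_csv()` writes the per-shape results table (fixed column
#' order, schema version in a comment-free header column set).
#' `write_battery_summary_json()` writes the percent-difference block, both
#' power-law fits, the AR > MIC/MCC count, and an echo of the full
#' configuration.
#'
#' @param battery A [run_battery()] table.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_battery_csv <- function(battery, path) {
  utils::write.csv(as.data.frame(battery), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_battery_csv
#' @export
write_battery_summary_json <- function(battery, path) {
  cfg <- attr(battery, "config")
  s <- summary(battery)
  payload <- list(
    schema = "fazmetrics-battery-summary-1",
    n_shapes = nrow(battery),
    percent_differences = s$percent_differences,
    roundness_power_law = s$roundness_fit[c("k", "p", "r_squared", "n_points", "fit_domain")],
    circularity_power_law = s$circularity_fit[c("k", "p", "r_squared", "n_points", "fit_domain")],
    ar_exceeds_micmcc = as.list(s$ar_exceeds),
    config = list(radii = cfg$radii, ratios = cfg$ratios,
                  n_samples = cfg$n_samples,
                  options = unclass(cfg$options)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
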