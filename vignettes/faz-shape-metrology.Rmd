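---
title: "FAZ shape metrology: conventions, algorithms, and their calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FAZ shape metrology: conventions, algorithms, and their calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fazmetrics)
```

## The measurement problem

The foveal avascular zone (FAZ) is segmented from OCTA angiograms as a
single binary region, and its shape is summarized by four families of
metrics: area, perimeter, circularity `4πA/P²`, and roundness. None of these
is a single number for a rasterized shape — each depends on the estimator:

* **Perimeter** is the worst offender. The length of a pixelized boundary
  depends on the unit of measurement (the coastline effect): walking pixel
  centers with unit and diagonal steps systematically over-measures a smooth
  outline by about 5.5 %, while walking pixel edges over-measures it by
  about 27 % (`8r` vs `2πr` for a disk). Production estimators therefore
  apply corner corrections, and different tools apply different ones.
* **Circularity** inherits the square of any perimeter bias.
* **Roundness** has two inequivalent definitions in routine use: the axis
  ratio of the best-fit ellipse (AR roundness, `MinorAxis/MajorAxis`,
  equivalently `4A/(π·MajorAxis²)` for an exact ellipse), and the area ratio
  of the maximum inscribed circle (MIC) to the minimum circumscribed circle
  (MCC). For an ideal ellipse with axis ratio `q` these are `q` and `q²` —
  related, but far from equal, and they respond differently to border
  irregularity: the moment-based ellipse fit averages over the whole region,
  while the MIC/MCC pair is extremal and is punished by every local
  indentation or protrusion.

The package computes all variants side by side, from both exact sub-pixel
boundary coordinates and rasterized masks, so that the differences can be
quantified rather than silently absorbed into "the" reported value.

## Sub-pixel reference measurements

A shape is represented exactly by a closed polygon of sub-pixel vertices.
The reference measurements are the shoelace area and the distance-formula
perimeter of that polygon, plus closed-form (circle) or quadrature (ellipse
arc length, relative tolerance `1e-12`, cross-checked against the Ramanujan
closed-form approximation) theoretical values for parametric shapes.

For synthetic circles and ellipses sampled at `n = 300` uniformly spaced
parameter values, the inscribed-polygon deficits are known in closed form
and — usefully for testing — are independent of both scale and aspect ratio:
the perimeter of the 300-gon falls short of the true perimeter by a relative
`1 − sinc(π/300) ≈ 1.83e-5` (0.00183 % as a symmetric percent difference)
and the area by `1 − sinc(2π/300) ≈ 7.31e-5` (0.00731 %), for every shape in
the battery. The acceptance suite asserts exactly these values.

## The simulation battery

`generate_battery()` builds 37 circles with radii spanning 2–1000 px plus,
for each radius, three ellipses of the same area with axis ratios 0.4, 0.6
and 0.8 (aspect ratios 10:4, 10:6, 10:8; semi-axes `a = r/√q`, `b = r·√q`).
The radii are not individually prescribed by the underlying experimental
design, so the package spaces them logarithmically (rounded to 4 significant
figures): pixel-domain bias is a function of shape size relative to the
pixel, and log spacing covers the small-shape regime — where bias changes
fastest — densely. The spacing is a configuration item (`battery_radii()`)
so linear or custom ladders can be substituted; fitted inter-metric
relations shift mildly (within a few percent) under such substitutions
because the radius ladder reweights the small-shape tail.

Parameter sampling is `t = 2πk/n`, `k = 0…n−1` — the endpoint is excluded so
all 300 vertices are distinct.

## Rasterization

A pixel belongs to the mask iff its center lies inside the polygon under the
even-odd rule. The implementation is a half-open scanline fill: an edge
covers scanlines `min(y) ≤ y < max(y)` and a crossing at `c` covers centers
from `⌈c⌉` up to (not including) the next crossing. Centers exactly on an
edge are a measure-zero case for trigonometric contours; the half-open rule
resolves them deterministically but, as a consequence, a rasterized disk is
not perfectly 4-fold symmetric — its moment axis ratio is typically within
`2e-3` of 1 rather than exactly 1. Tests assert against the brute-force
per-pixel point-in-polygon oracle. No anti-aliasing or fractional coverage
is modelled; masks are strictly binary, matching segmentation outputs.

`upsample_mask()` performs nearest-neighbour replication (each pixel becomes
an `f × f` block), the operation applied to low-resolution angiograms before
segmentation. Replication preserves the blocky boundary, so it does not by
itself reduce perimeter bias; re-rasterizing a contour at a finer scale does,
and the test suite demonstrates that distinction.

## Pixel-domain estimators and their constants

All constants live in `faz_options()` so a run is reproducible from its
echoed configuration, and so each convention can be calibrated against the
tool it replicates.

* `perimeter_chain8()`: length of the Moore-traced boundary path, 1 per
  axial and `√2` per diagonal step (the historical regionprops-style
  perimeter). Boundary tracing is canonicalized — clockwise on screen,
  starting at the top-most/left-most foreground pixel — so values are
  deterministic. Asymptotic bias on a disk: about +5 %.
* `perimeter_corner_weighted()`: `0.980·N_axial + 1.406·N_diag −
  0.091·N_corner` (Vossepoel–Smeulders weights; the modern
  regionprops-style perimeter). Near-unbiased on smooth shapes (−0.3 % at
  r = 200).
* `perimeter_traced()`: the particle-analysis outline estimator. The crack
  outline (pixel edges between foreground and background) is decomposed into
  axis-aligned sides; unit-step staircase corners are counted alternately
  and each counted corner converts two weighted unit edges (`2 × 0.948`)
  into one diagonal step (`1.340 = 0.948·√2`). Near-unbiased on smooth
  shapes. A plain "crack length minus `(2 − √2)` per convex corner" variant
  is available (`style = "corner_deficit"`) but is biased low by ~10 % on
  smooth shapes and is not the default.
* `fit_ellipse_moments()`: second central moments of the foreground pixel
  centers with the `+1/12` pixel-extent variance correction; full axes are
  `4·√eigenvalue` (`moment_normalized`), or rescaled so the ellipse area
  equals the pixel count (`equal_area`). The axis ratio — hence AR roundness
  — is identical between the two normalizations, which is why the two
  software conventions report identical roundness despite different axis
  lengths.
* `software_circularity()`: regionprops-style uses the corner-weighted
  perimeter, optionally with the small-region correction
  `(1 − 0.5/ρ)²`, `ρ = P/2π + 0.5` (off by default, see below);
  particle-analysis-style uses the chain-code perimeter by default and caps
  at 1.0. The chain-code choice reflects a documented quirk of particle
  analysis: its Perimeter column and the perimeter inside its circularity
  are not the same estimator, which is why the circularity it reports for a
  large rasterized circle sits near 0.9 rather than 1.0.

### Why these defaults

The corner-rule and circularity defaults were chosen so that the package's
two software conventions reproduce each other's published cross-calibration
behaviour on the battery: with the chain-code circularity denominator and
the uncorrected regionprops-style circularity, the inter-convention relation
is a clean power law with coefficient ≈ 0.9 and exponent ≈ 1 over resolved
shapes (the `summary()` output of a battery run computes it). With the
corrected or traced-perimeter variants instead, the relation degenerates
(capping and small-region shrinkage decouple the two axes at small sizes).
Both alternatives remain available as flags.

## Extremal circles

`min_circumscribed_circle()` is an exact Welzl-style randomized incremental
solver (convex-hull pruned, insertion order shuffled under a fixed internal
seed for determinism, support-point residual tolerance `1e-9`); the test
suite checks it against an `O(n³)` pair/triple enumeration oracle.
`max_inscribed_circle()` seeds at the maximum of the exact Euclidean
distance transform (ties broken towards smallest `(y, x)`), interpolates the
peak quadratically, and refines by direct Nelder–Mead ascent of the distance
function; refinement is disableable for strict grid semantics.

Because neither extremal circle is well-defined for a pixel set without
choosing a boundary representation, both solvers take a `reference`:

* MIC default `"background_centers"`: the raw distance-transform value,
  i.e. distance to the nearest background pixel center.
* MCC default `"boundary_centers"`: smallest circle enclosing the boundary
  pixel centers.
* Alternatives: `"crack"` (pixels as unit squares) for the MIC;
  `"pixel_corners"` and `"contour"` for the MCC.

The default pair matches the semantics of the mask-consuming utilities
used in OCTA pipelines (a distance-transform MIC and a point-set MCC), but
it is deliberately *not* internally nested: the MIC reference sits about
half a pixel outside the MCC reference, so on a rasterized near-circle the
MIC/MCC area ratio lands marginally above 1 while the moment-based AR
roundness is (almost exactly) 1. The nested alternatives (`"crack"` +
`"pixel_corners"`, or both on `"boundary_centers"`) keep the ratio strictly
below 1 instead. This half-pixel convention choice is invisible for
well-resolved shapes but flips the sign of `AR − MIC/MCC` for rasterized
circles, which is why the battery's AR-dominance count is reported together
with its convention and why the count is the statistic most sensitive to
an upstream tool's undocumented conventions: under the default it is
111/148 — every ellipse dominates and no rasterized circle does — while
nested references move the rasterized circles to the other side of the
equality. Real, irregular FAZ shapes are far from the equality boundary and
are unaffected by the choice.

For ideal geometry the identity `MIC/MCC = AR²` holds exactly (MIC radius
`b`, MCC radius `a`), and a noiseless log–log fit across ideal ellipses
returns coefficient 1, exponent 2, R² = 1 — asserted to `1e-9`.

## Inter-metric power laws

`fit_power_law()` fits `y = k·xᵖ` by least squares on `log y ~ log x`; R² is
reported in log space (where the fit is linear), with a linear-space R²
alongside for transparency. The battery relations
(`relate_roundness()`, `relate_circularities()`) are fitted by default over
each relation's validity domain — shapes at least 6 px across for the
roundness relation and at least 16 px for the circularity relation. Below
those diameters the extremal-circle radii and capped circularities are
dominated by pixel quantization and the relations visibly break; the
include-all fits are one argument away (`min_diameter_px = 0`) and are
reported by the battery summary JSON as a sensitivity check.

## The FAZ-like blob generator

`make_faz_blob()` emulates a segmented FAZ as a radial Fourier perturbation
of a circle: `r(θ) = r₀(1 + Σₖ aₖ cos(kθ + φₖ))`, harmonics `k = 2…8`,
amplitudes uniform in `±irregularity/k`. The `1/k` spectral decay produces
the smooth, gently lobed borders seen in healthy FAZs; `irregularity < 0.5`
guarantees a simple star-shaped curve. Defaults (mean radius 35 px,
irregularity 0.2, on a 304-px grid with a 3 mm field of view) give areas
around 0.38 mm², inside the normal range. The generator is deterministic per
seed and draws from a private RNG stream so it never perturbs the caller's
random state.

What the blobs do *not* emulate: segmentation noise (single-pixel spurs,
staircase artifacts from thresholding), capillary-notch concavities deeper
than the harmonic model allows, holes, or multi-lobed pathology. Passing
tests on blobs therefore validate the measurement chain on clean,
FAZ-plausible geometry; they do not certify behaviour on adversarial
segmentations, where only the single-region precondition is enforced
(multi-component masks are rejected rather than silently merged).

When a real mask is measured (`measure_real_mask()`), no sub-pixel contour
exists; the exact boundary of the pixel region is its crack outline, and the
"sub-pixel" area and perimeter columns then measure that polygon. The area
equals the pixel count exactly; the perimeter is the staircase length and
carries the corresponding coastline bias relative to the smooth pre-raster
shape — an irreducible limitation of mask-only input, and the reason
sub-pixel coordinates should be preserved whenever the segmentation can
produce them.

## Numerical choices and degenerate inputs

* Quadrature: ellipse arc length to `1e-12` relative tolerance on one
  quadrant.
* Rasterization tie-breaks: half-open in both axes (lower-left inclusive).
* Boundary tracing: terminates when the post-start state recurs, which
  handles one-pixel-wide spurs (traversed out and back) without special
  cases; a single-pixel region yields a one-point path and zero chain-code
  perimeter.
* Welzl collinear triples fall back to the widest two-point circle.
* Degenerate contours (zero enclosed area), empty masks, multi-component
  masks, non-positive scales and out-of-range parameters raise errors early
  with specific messages; nothing is silently clamped.
* Masks with holes: holes are not counted in the area and do not contribute
  to the outer boundary (the tracers follow the outer outline only).

## Problem sizes

The default battery (148 shapes up to radius 1000 px, i.e. masks up to
about 2000 × 2000) measures in roughly one to two minutes on a single core,
dominated by the distance transforms of the largest masks; the test suite
computes the full battery once and shares it across battery-wide checks.
Property-style checks (solver-vs-oracle, isoperimetric bounds on generated
blobs) use 100 seeded cases each.
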