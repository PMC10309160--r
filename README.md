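# fazmetrics

Shape metrology for the foveal avascular zone (FAZ) and other single-region
binary masks.

The FAZ — the capillary-free region at the center of the retinal fovea,
segmented from OCTA images — is routinely summarized by area, perimeter,
circularity, and roundness. These metrics sound unambiguous but are not:
different analysis tools use different perimeter estimators on rasterized
shapes, "roundness" has at least two inequivalent definitions, and
pixel-domain measurements diverge from exact (sub-pixel) boundary
measurements most severely for small shapes. `fazmetrics` implements every
variant side by side so the differences can be quantified, calibrated
across, and reported transparently:

* **Sub-pixel metrics** from exact boundary coordinates: shoelace polygon
  area, distance-formula perimeter, circularity `4πA/P²` (and its ISO
  square-root variant).
* **Pixel-domain metrics** replicating the two software conventions in
  common use: foreground pixel-count area; chain-code, corner-weighted
  (Vossepoel–Smeulders) and traced-outline perimeters; regionprops-style and
  particle-analysis-style circularity; moment-based best-fit ellipse under
  two normalizations.
* **Roundness**: AR roundness (minor/major axis of the best-fit ellipse,
  `4A/(π·MajorAxis²)`) and MIC/MCC roundness (area ratio of the maximum
  inscribed to the minimum circumscribed circle), with an exact Welzl
  smallest-enclosing-circle solver and a distance-transform maximum
  inscribed circle solver.
* **A simulation battery**: 37 circles with radii from 2 to 1000 px plus
  three same-area ellipses each (aspect ratios 10:4, 10:6, 10:8), used to
  quantify algorithm-induced bias and to fit the inter-metric power-law
  relations `MIC/MCC = k·AR^p` and the circularity cross-calibration between
  software conventions.

## Worked example

Measure a synthetic FAZ-like blob (35 px mean radius on a 304-px grid with a
3 mm field of view, i.e. scale 3/304 mm/px) under every algorithm at once:

```r
library(fazmetrics)

blob <- make_faz_blob(seed = 42, mean_radius = 35, irregularity = 0.2)
m <- measure_shape(blob, scale_mm_per_px = 3 / 304)
t(round(m[, c("area_px", "area_mm2", "perimeter_subpixel", "perimeter_mm",
              "perimeter_corner_weighted", "perimeter_chain8",
              "perimeter_traced", "circ_subpixel", "circ_matlab_style",
              "circ_imagej_style", "ar_roundness", "mic_mcc_roundness")], 4))
#> area_px                   3869.0000
#> area_mm2                     0.3769
#> perimeter_subpixel         225.0619
#> perimeter_mm                 2.2210
#> perimeter_corner_weighted  222.0720
#> perimeter_chain8           233.1371
#> perimeter_traced           221.4160
#> circ_subpixel                0.9602
#> circ_matlab_style            0.9859
#> circ_imagej_style            0.8945
#> ar_roundness                 0.8484
#> mic_mcc_roundness            0.6824
```

The numbers illustrate the package's central point: one shape, one area
(0.38 mm², a typical normal FAZ), but three pixel-domain perimeters spanning
221–233 px around the exact 225.1 px value; a chain-code-based circularity
(0.89) well below the corner-weighted one (0.99); and two "roundness" values
(0.85 vs 0.68) that are not interchangeable — AR roundness, driven by the
best-fit ellipse, is robust to border irregularity, while MIC/MCC roundness
is punished by every local indentation.

Battery-level analyses:

```r
tab <- run_battery()               # 148 shapes, ~1-2 min
summary(tab)                       # percent differences, power laws, counts
relate_roundness(tab)              # MIC/MCC = k * AR^p over resolved shapes
relate_circularities(tab)          # particle-analysis vs regionprops circ
```

A thin command-line interface wraps the same functions:

```sh
fazmetrics battery --out-csv results.csv --out-json summary.json
fazmetrics measure --mask faz.png --scale-mm-per-px 0.00987
fazmetrics simulate --seed 1 --n 5 --out-dir fixtures/
```

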