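Package: fazmetrics
Title: Shape Metrology for the Foveal Avascular Zone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes shape biomarkers of the foveal avascular zone (FAZ) and
    other single-region binary masks: area, perimeter, circularity, aspect-ratio
    (AR) roundness, and maximum-inscribed to minimum-circumscribed circle
    (MIC/MCC) roundness. Each metric is available both from exact sub-pixel
    boundary coordinates and from pixel-domain estimators replicating the two
    software conventions in common use for OCTA image analysis (regionprops-style
    and particle-analysis-style). Includes a synthetic circle/ellipse battery and
    FAZ-like blob generator for quantifying how the choice of algorithm changes
    the reported metrics, plus power-law calibration between metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
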