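Package: iopcharts
Title: Digitization and Analysis of Hand-Drawn 24-Hour Intraocular Pressure Charts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digitizes scanned hand-drawn 24-hour (nycthemeral) intraocular
    pressure (IOP) charts of the standard German inpatient form into
    structured per-eye IOP time series. The pipeline binarizes the scan with
    adaptive Gaussian thresholding, locates the chart frame as the largest
    contour reduced to a quadrilateral by Douglas-Peucker approximation,
    warps it to a canonical geometry, detects the time gridlines with an
    edge-based Hough transform, segments the blue (right eye) and red (left
    eye) marks with HSV color masks, and converts mark positions to
    timestamped IOP values through the form's piecewise-linear pressure
    axis. Also included: header metadata extraction (handwritten date
    digits, machine-printed name labels), a ground-truthed synthetic chart
    renderer and cohort simulator, extraction-accuracy evaluation (false
    positive/negative rates, value distance), and clinical IOP statistics
    (nycthemeral summary metrics, mean ocular perfusion pressure, acrophase
    alignment, cutoff contingency and ROC analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    nnet,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jpeg,
    digest,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
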