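Package: angioflow
Title: Color-Coded Parametric Angiography by Mask Subtraction and Temporal Variance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction of time-to-peak and bolus passage-time parameters from
    angiographic frame sequences by two independent processing pathways:
    classical mask-subtraction digital subtraction angiography (DSA) and
    digital variance angiography (DVA), which maps the temporal standard
    deviation of the raw, unsubtracted acquisition. Includes a synthetic
    contrast-bolus phantom generator with known ground-truth arrival times,
    circular region-of-interest time-density curve extraction, color-coded
    parametric map rendering (hue encodes arrival time, brightness encodes
    amplitude), Pearson-correlation agreement reports between the two
    pathways, and an end-to-end simulated study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
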