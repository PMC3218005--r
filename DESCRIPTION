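Package: confluency
Title: Vision-Based Confluency Monitoring, Growth Forecasting and Adaptive
    Subculture Planning for Time-Lapse Phase-Contrast Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automating the decision of when to passage adherent
    cell cultures from phase-contrast time-lapse imaging. Frames are
    restored to suppress halo and shade-off artifacts, thresholded and
    dilated into binary confluency masks, and the covered-area fraction is
    averaged across fields of view. A sliding-window second-order
    polynomial fit forecasts confluency hours ahead and estimates when a
    user-defined threshold (default 0.5) will be crossed; an idempotent
    notification state machine emits a one-time advance alert and a
    one-time threshold reminder through pluggable channels. A cell-yield
    calculator plans serial 1:8 subcultures toward a target cell number.
    Includes a synthetic-data module that renders phase-contrast-like
    images with ground-truth masks and noisy growth curves, pixel-level
    precision/recall evaluation against reference masks, model-family
    comparison by forecast RMSE, and a batch/watch pipeline with a static
    report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
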