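Package: myotracer
Title: Vessel Diameter Tracking for Pressure Myography Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Offline diameter tracking for pressure-myograph recordings of
    transilluminated, pressurized blood vessels. Detects the outer and inner
    wall on each of a set of equally spaced scan lines as peaks in the
    derivative of the transmural intensity profile, rejects outlying scan
    lines with the modified z-score, calibrates pixel measurements to
    microns, and assembles gated time series with telemetry, user events and
    a three-file CSV export plus overlay-annotated TIFF frames. Includes a
    synthetic vessel-phantom generator with known ground-truth diameters
    (constant, step and vasomotion dynamics), a bang-bang bath-temperature
    simulator and a hydrostatic pressure-head converter, so the whole
    pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    methods,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
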