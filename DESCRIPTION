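Package: vispec
Title: Virtual Instrument Toolkit for Miniature Transmission Spectrophotometry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A hardware-free computational stack for low-cost visible-range
    transmission spectrophotometers built around CMOS line sensors. Provides a
    seeded virtual instrument (LED source models, Beer-Lambert sample
    transmission, Gaussian slit blur, additive dark noise, 10-bit
    quantization), dark correction and frame accumulation, single-beam
    absorbance computation with quality flags, instrument figures of merit
    (RMS dark noise, dynamic range, signal-to-noise ratio, wavelength accuracy
    from emission-peak maxima), and analytical calibration statistics
    (ordinary least squares fits with R-squared, limits of detection and
    quantification from the intercept standard error, intra- and inter-day
    relative standard deviation, inverse prediction). Includes plain-text CSV
    and JSON interchange formats and a command-line interface covering single
    and continuous measurement modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
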