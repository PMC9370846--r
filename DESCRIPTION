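Package: herdrhythm
Title: Circadian Periodicity Intensity of Herd Activity from Collar Accelerometers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning raw triaxial collar-accelerometer streams from
    young livestock into per-animal 24 h periodicity-intensity traces and
    herd-level synchrony analyses. The pipeline computes the signal vector
    magnitude, applies a zero-phase Butterworth band-pass filter, rectifies
    and aggregates into fixed epochs, then slides a 7-day window in 15-minute
    steps, scoring the strength of the 24 h circadian component in each window
    as the variance explained by a best-fit diurnal sinusoid (equivalently the
    standard-normalised Lomb-Scargle periodogram at the 24 h frequency, robust
    to missing epochs from collar-off gaps). Herd-level functions align animal
    traces on a common grid, exclude animals with excessive missing data,
    build stacked aggregates, validate them by sub-group resampling, and flag
    individual animals deviating from herd-synchronous change. A synthetic
    herd simulator with known circadian amplitudes, acclimatisation ramps,
    shared welfare dips and collar-off gaps provides ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tibble,
    ggplot2,
    patchwork,
    readr,
    rlang,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
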