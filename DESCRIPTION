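Package: myowave
Title: Waveform Metrics from Smooth-Muscle Contractility Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying contraction waves in ex vivo fluorescence
    time-lapse recordings of tubular smooth-muscle organs such as the mouse
    uterine horn. Detects the organ's upper and lower boundaries in every
    frame with a weighted Sobel edge index, builds area- and intensity-based
    spatiotemporal (Hovmoller) maps, computes waveform metrics (amplitude,
    period, frequency, velocity, wavelength, direction) globally and per
    uterine segment from user-marked wave annotations, compares groups with
    exact or approximate Mann-Whitney tests after ROUT outlier removal, maps
    pre-implantation embryo positions along the horn, and generates synthetic
    contracting-tube videos with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
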