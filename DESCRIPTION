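Package: ciliawave
Title: Waveform Analysis of the Traveling-Wave Beat of Cilia and Flagella
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the beat of isolated, reactivated axonemes from
    digitized centerline coordinates. Converts Cartesian centerlines to the
    tangent-angle representation, removes the rigid-body rotation of
    circularly swimming axonemes by LOESS detrending of the leading tangent
    angle, decomposes the beat into static (time-averaged) and dynamic
    components, and estimates the dynamic-beat wavelength with a
    finite-window Fourier estimator averaged over beat cycles. Also provides
    beat-frequency estimation by discrete Fourier transform with parabolic
    peak interpolation, wave velocimetry by tracking zero crossings of the
    tangent angle, a nonparametric crossing-count test for comparing
    wavelength-versus-length data between preparations, closed-form
    low-Reynolds-number quantities (Machin number, propulsive force per unit
    length, swimming speed), and a synthetic traveling-wave beat generator
    used to validate the estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
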