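Package: RamanAMM
Title: Amplitude-Mode-Model Analysis of Resonance Raman Frequency
    Dispersion in Pigmented Feathers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for in-situ resonance Raman analysis of conjugated
    polyene pigments (psittacofulvins) in feather barbs. Provides S4
    containers for Raman spectra, excitation series and hyperspectral
    grids; a preprocessing chain (spectral cropping, Savitzky-Golay
    smoothing, asymmetric-least-squares or polynomial baseline
    correction, 0-1 intensity normalization, replicate averaging);
    localization and tracking of the pigment C-C and C=C stretching
    bands across excitation wavelengths; amplitude-mode-model frequency
    dispersion fitting (product-rule electron-phonon coupling and
    dispersion rate D with regression diagnostics); band-sum
    hyperspectral mapping with an emission index; a hue-trend summary
    for multi-feather surveys; and a fully parameterized synthetic
    spectrum generator so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
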