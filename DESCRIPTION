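Package: leafplates
Title: Two-Layer Plate Models and Evolutionary Inversion for Leaf Optical Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of leaf reflectance and transmittance over
    400-1000 nm with generalized plate (Stokes) radiative-transfer models,
    including a two-layer variant in which chlorophyll, water and dry matter
    are partitioned between an upper and a lower optical layer, as observed
    in rice leaves.  Layer parameters are retrieved from measured spectra by
    an in-package NSGA-III evolutionary optimizer with a relative-deviation
    fitness.  Includes spectral utilities (1 nm resampling, Savitzky-Golay
    smoothing), wet-lab conversion formulas for leaf biochemistry, synthetic
    cohort generation for testing, band-segmented RMSE evaluation against a
    uniform-leaf baseline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
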