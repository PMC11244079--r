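Package: pipmorph
Title: Outline Morphometrics and Discriminant Classification of Grape Pips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for seed outline morphometrics built around elliptic
    Fourier descriptors of grape-pip silhouettes. Provides contour tracing
    of binary seed images, equal arc-length resampling, closed-form elliptic
    Fourier coefficients with size/start-point normalisation and
    harmonic-power diagnostics, stepwise linear discriminant analysis with
    Wilks' lambda entry and removal criteria, leave-one-out cross-validation,
    and a two-stage classification pipeline that first separates wild from
    domesticated pip morphotypes and then assigns domestic-classified seeds
    to individual cultivars, with percentage-allocation reports by berry
    colour and geographic origin. A synthetic silhouette generator with
    controllable class separation emulates reference and archaeological
    populations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    MASS,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
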