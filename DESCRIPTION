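Package: tissuemech
Title: Tensile, Viscoelastic and AFM Nano-Mechanical Analysis of Soft Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes raw mechanical-test exports for soft biological
    membranes: tensile stress-strain curves (Young's modulus over a window of
    the failure strain, failure point detection, engineering-to-true
    conversion), ramp-and-hold stress relaxation fitted with a generalized
    Maxwell (Prony series) model including chi-square-drop selection of the
    number of elements, and atomic force microscopy nano-mechanics (photodiode
    force calibration, friction-loop processing to a coefficient of friction,
    and Hertzian sphere-on-flat modulus fitting). Seeded synthetic generators
    emulate every input type from known ground truth so the whole pipeline is
    testable by parameter recovery.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
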