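Package: biophoton
Title: Biophoton-Based Quality Assessment of Fresh Medicinal Herbs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality assessment of fresh plant material from
    ultra-weak photon emission measurements. Reads binned photon-count time
    series, computes background-corrected spontaneous-emission rates (CPS),
    fits the hyperbolic Gu decay model to delayed-luminescence curves to
    derive the initial intensity I0 and coherence time T, quantifies leaf
    pigments from three-wavelength absorbance readings, and runs the
    group-comparison (Student's t-test) and Pearson-correlation analysis
    linking biophoton parameters to active-ingredient content. Includes a
    Poisson photon-stream simulator that generates complete synthetic study
    cohorts with known ground truth for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
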