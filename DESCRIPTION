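Package: fvri
Title: Fractional Vessel Remodeling Index for Intravascular Ultrasound Pullbacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies coronary artery remodeling from intravascular
    ultrasound (IVUS) pullback measurements using the fractional vessel
    remodeling index (FVRI), which compares each cross-section's measured
    vessel area against its inferred pre-disease dimension. Provides a
    bootstrap multivariable linear model of normal external elastic membrane
    area from constitutional and anatomical covariates (with a packaged
    published default), per-frame and per-lesion remodeling scoring and
    four-pattern classification, the classical reference-based remodeling
    index for comparison, agreement tables, virtual-histology composition
    contrasts, a synthetic pullback simulator with known ground truth, and
    reporting utilities.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
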