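Package: hemopump
Title: Impeller Design Calculus and In Vitro Hemolysis Analysis for
    Centrifugal Blood Pumps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design calculus for radial impellers of bearingless centrifugal
    blood pumps (Euler specific work with slip correction, Cordier sizing via
    diameter number and specific speed, required-speed maps over blade angle
    and height, optimal eye radius) together with an analysis pipeline for in
    vitro hemolysis assays: absorbance calibration, plasma-free-haemoglobin
    regression, the normalized index of hemolysis (NIH), normalization to a
    session reference pump, and Welch-test benchmarking of pump variants.
    Includes a seeded synthetic-study generator with known ground truth for
    validating every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
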