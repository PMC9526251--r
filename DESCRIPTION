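Package: microqc
Title: Quality-Control Metrics for Fluorescence Light Microscopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Routine quality-control analyses for fluorescence light
    microscopes: point-spread-function (PSF) resolution measurements from
    sub-resolution bead stacks, field-illumination uniformity and centering,
    chromatic channel co-registration, illumination-power stability, stage
    drift and positioning repeatability, and dark-frame camera noise
    characterization (offset, DSNU, read-noise maps). Each analysis reports
    the field's standard metrics together with tolerance-based pass/fail
    flags, and a synthetic-fixture generator provides ground-truth data for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    EBImage,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
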