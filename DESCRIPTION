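Package: segmapr
Title: Segmental Body-Map Analysis of Digital Symptom Drawings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing digital body drawings of referred segmental
    signs and spontaneous visceral pain. Provides a schematic front/back
    segmental body atlas (trigeminal, cervical, thoracic, lumbar, sacral and
    coccygeal dermatome bands), rasterization of polygon drawings onto the
    atlas grid, per-segment and per-half-segment coverage statistics with a
    configurable inclusion threshold, lateralization and frequency summaries,
    mean cohort body maps, a synthetic patient-cohort generator encoding
    organ-specific segment spans and the Hansen-Schliack side rule, and an
    end-to-end reporting pipeline with CSV/JSON/NIfTI/PNG outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    RNifti,
    png,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
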