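Package: sinusmorph
Title: Landmark Morphometry of the Posterior Maxillary Sinus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landmark-based morphometric analysis of the posterior
    maxillary sinus on coronal CT slices. Converts manually placed pixel
    landmarks to millimetres via digital-ruler calibration, aggregates
    replicate observer measurements into consensus points with gross-error
    flagging, computes sinus depth (signed distance of the deepest sinus
    floor point from the hard-palate line), residual alveolar ridge height
    and the sinus opening angle, derives a quartile-based three-class sinus
    classification, and compares groups with one-way and additive
    multi-factor analysis of variance. Includes a seeded synthetic-cohort
    generator that simulates class-structured sinus anatomy and renders it
    to replicated landmark sheets, so the full pipeline can be exercised
    and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
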