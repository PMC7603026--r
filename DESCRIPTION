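Package: cytomotion
Title: Quantification of Cancer Cell Motility and Cytoskeletal Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based quantification of cancer cell motility and
    cytoskeletal organization in wound-healing (scratch) assays under
    alternating electric field treatment. Provides per-cell morphometry
    (area, nucleus-to-centroid polarity distance, background-subtracted
    fluorescence intensity, minimal-bounding-rectangle orientation relative
    to the wound frontline), classification of microtubule-organizing
    center (MTOC) position, focal-adhesion punctum detection and
    quantification, single-cell migration-track statistics (accumulated
    and Euclidean distance, directionality, velocity), spheroid dispersal
    ratios, detachment kinetics, the associated inferential tests, and
    seeded synthetic-data generators with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    withr
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
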