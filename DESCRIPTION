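Package: mblq
Title: Quantification of Peri-Implant Marginal Bone Loss in Intraoral
    Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures peri-implant marginal bone resorption in intraoral
    (periapical and bitewing) radiographs. Starting from a grayscale
    radiograph and rough crown/screw bounding boxes produced by an object
    detector, the pipeline classifies the jaw side, validates crown-screw
    associations, extracts screw edges (gamma enhancement and Canny),
    describes them with a polar Hough transform and least-squares
    degree-2 polynomial fits, locates the two critical points per edge by
    perpendicular intensity-profile scanning, and reports bone-resorption
    percentages, severity classes and millimetre quantities. Includes the
    matching-score and t-test evaluation statistics, and a synthetic
    radiograph phantom generator with full ground truth so that every
    stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
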