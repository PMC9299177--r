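Package: craniosort
Title: Osteometric and 3D Surface Screening for Cranium-Atlas Sorting in
    Commingled Remains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for re-associating, or more realistically excluding, crania
    and first cervical vertebrae (atlases) in commingled skeletal assemblages
    via the atlanto-occipital joint. Implements two screening arms: an
    osteometric arm that builds the exhaustive cranium-by-atlas pairwise
    difference dataset from sixteen linear measurements of the occipital
    condyles and atlas superior articular facets and evaluates six supervised
    classifiers with skew-aware metrics (positive predictive value under
    heavy class imbalance), and a 3D arm that rigidly superimposes articular
    surface patches (landmark least-squares initialisation followed by
    iterative closest point refinement), summarises point-to-surface distances
    as RMS, and derives a maximum-of-matches exclusion threshold. Calibrated
    synthetic generators for measurement populations, superimposition RMS
    outcomes and articular surface meshes make the whole pipeline testable
    without access to the original skeletal collection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    car,
    e1071,
    jsonlite,
    mgcv,
    pROC,
    stats,
    utils,
    graphics,
    grDevices,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
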