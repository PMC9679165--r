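Package: fcdetect
Title: Surface-Based Detection of Focal Cortical Dysplasia from Vertex-Wise
    MRI Features
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end surface-based pipeline for detecting focal
    cortical dysplasia (FCD) from per-vertex cortical features on a
    bilaterally symmetric template surface: automated quality control,
    multi-site ComBat harmonization, three-stage feature normalization
    (intrasubject z-scoring, interhemispheric asymmetry, per-vertex control
    normalization), an ensemble of focal-loss multilayer perceptrons with
    class-balanced vertex sampling and a Dice-optimal decision threshold,
    geodesic border zones around lesion masks, cluster-level evaluation
    metrics, and interpretable per-patient reports based on integrated
    gradients. Includes a fully synthetic multi-site cohort generator so
    every stage is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    igraph,
    jsonlite,
    mclust,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    sva,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
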