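Package: cereplaq
Title: 3D Morphometry of Amyloid Plaques in Phase-Contrast Tomography Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies beta-amyloid plaque morphology in three-dimensional
    X-ray phase-contrast tomography volumes of cerebellar cortex.
    Implements semi-automatic plaque segmentation (cylindrical volumes of
    interest around seed regions, bimodal gray-level thresholding, connected
    components, minimum-volume filtering), Hessian-eigenvalue blobness
    detection of near-spherical Purkinje somata, per-object morphometry
    (volume, iso-surface area, sphericity, principal-axis orientation), and
    population statistics (log-normal volume checks, sphericity summaries
    and group comparison, undirected axial orientation statistics). Includes
    a seeded synthetic phantom generator that emulates the layered cerebellar
    cortex with ground-truth object records, so the whole pipeline is
    testable without tomographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png,
    rhdf5,
    e1071,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
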