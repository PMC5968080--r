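Package: disc3d
Title: Multi-View Focus-Stack Digitization of Pinned Specimens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational pipeline for all-sided digitization of pinned
    insect specimens from focus stacks: spherical pose-program generation
    for a two-axis gimbal, calibrated perspective-consistent extended
    depth-of-field (EDOF) compositing, back-light silhouette masking,
    shape-from-silhouette visual-hull reconstruction, and mesh
    morphometry with measurement-reliability statistics.  A built-in
    synthetic scanner renders focus stacks of analytic scenes through a
    thin-lens camera on a macro rail, providing ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
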