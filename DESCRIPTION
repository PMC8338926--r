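Package: octapattern
Title: Retinal Microvascular Orientation Patterns from En Face OCTA Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the pattern of retinal microvascular orientation in
    en face optical coherence tomography angiography (OCTA) images. A
    multiscale Hessian vesselness filter estimates a per-pixel vessel
    likelihood, width scale and axial orientation; a global Otsu threshold
    builds a binary vessel mask; the macular region is partitioned into a
    5-mm disk with eight equal-area 45-degree anatomical sectors; and each
    sector's axial orientation distribution is summarised by three pattern
    metrics (preferred orientation, vessel anisotropy, vessel area) together
    with the conventional vessel density. Includes a synthetic-scene
    generator with ground truth for validation, axial circular statistics,
    and the nonparametric group comparisons used for sectoral analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
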