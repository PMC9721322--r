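Package: robustmask
Title: Robust Bad-Pixel Mask Generation for X-Ray Pixel Detectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automatic generation of bad-pixel masks for integrating and
    photon-counting X-ray pixel detectors used in serial crystallography.
    Per-pixel features (dark offset, dark noise, gain-indicator separability
    and level, and statistical separability from the local background under
    near-flat illumination) are extracted from dark-field and flat-field
    frame stacks; Gaussian and planar models are fitted robustly to each
    feature so that a bounded fraction of defective pixels cannot bias the
    model, and pixels whose feature SNR exceeds a single global threshold
    are flagged. Masks are encoded as one 8-bit code per pixel per memory
    cell and gain stage, with a bit per flagging feature, and written to
    HDF5 alongside the configuration needed to reproduce them. A seeded
    synthetic-detector generator with ground-truth defect populations makes
    the whole pipeline testable without facility data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    parallel,
    stats,
    utils,
    tibble,
    ggplot2,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: HDF5 C library (libhdf5)
Config/testthat/edition: 3
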