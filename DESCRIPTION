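Package: pseudotract
Title: Cohort-Specific Pseudo-Atlas Diffusion Tensor Tractography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for semi-automated white matter tract
    analysis from diffusion-weighted MRI. Fits the diffusion tensor by
    log-linear least squares, derives fractional anisotropy and diffusivity
    maps, performs deterministic whole-brain streamline tractography, and
    isolates named white matter tracts with declarative AND/NOT region-of-
    interest recipes. A cohort-specific pseudo-atlas workflow propagates the
    recipe gates from one template subject to the rest of a cohort via affine
    registration of fractional anisotropy maps, with optional prior alignment
    of the anterior and posterior commissures (ACPC). An atlas-label
    comparator extracts per-tract metrics from a user-supplied label volume.
    Downstream tools compute Evans' index ventriculomegaly measurements,
    scaled radar and along-tract diffusion profiles, and paired inter-method
    comparison statistics. A digital phantom generator produces synthetic
    multi-bundle diffusion cohorts with known ground truth so that every
    stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
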