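Package: ktjoint
Title: Joint Compressed Sensing and Parallel Imaging Reconstruction for
    Dynamic MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage reconstruction of accelerated dynamic (cine) cardiac
    MRI from uniformly-plus-randomly undersampled Cartesian k-t data. Stage
    one recovers a uniformly undersampled k-space per coil by FOCUSS
    iteratively-reweighted l2 minimization in the x-f (space by temporal
    frequency) domain; stage two fills the remaining phase-encode lines with
    a nonlinear GRAPPA kernel (truncated second-order polynomial) calibrated
    on auto-calibration lines. Includes the tailored k-t sampling-mask
    generator (uniform lattice times Gaussian-tapered random subset plus
    ACS block), complex scaling normalization between the stages,
    root-sum-of-squares coil combination, NMSE and temporal-profile metrics,
    a dynamic multi-coil cine phantom for simulation studies, and harnesses
    that sweep acceleration splits and ACS counts at a fixed net reduction
    factor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    optparse
Config/testthat/edition: 3
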