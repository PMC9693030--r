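Package: lungmech
Title: Lung Biomechanics from Deformable Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes biomechanical maps (Jacobian determinant, anisotropic
    deformation index, slab-rod index) from displacement vector fields relating
    expiration and inspiration lung CT volumes, evaluates registration quality
    with lobe Dice, worst-10% surface error, vessel-tree position error and
    symmetric closest-skeleton error, performs tissue-volume-preserving
    B-spline registration, and runs cohort-level regional trend and
    Bland-Altman agreement analyses. Includes a synthetic phantom generator
    with closed-form deformation gradients so the full pipeline is testable
    against analytic ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
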