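Package: dcsd
Title: Deep Constrained Spherical Deconvolution for Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of fiber orientation distribution functions (fODFs)
    from single-shell diffusion-weighted MRI. Provides an even-order real
    spherical-harmonic representation layer, single-shell single-tissue
    constrained spherical deconvolution (CSD), a 3x3x3-patch convolutional
    neural estimator trained with an explicit scan/rescan reproducibility
    loss and a gradient-direction-dropout augmentation, angular correlation
    coefficient (ACC) evaluation, and a synthetic scan/rescan phantom
    generator with analytic ground-truth fODFs for validation at desk scale.
    Reads and writes NIfTI volumes with FSL-style bvec/bval gradient tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
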