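Package: dtivba
Title: Diffusion Tensor Group Analysis with Voxel-Based Statistics and
    Synthetic DWI Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for group studies of ex vivo
    diffusion-weighted MRI of the developing brain: brain extraction from
    the isotropic diffusion-weighted image, per-voxel diffusion-tensor
    fitting with scalar and Westin shape maps (FA, ADC, axial and radial
    diffusivity, linearity, planarity, sphericity), whole-brain and
    FA-thresholded white-matter group comparisons, ROI summaries, and
    voxel-based analysis with multi-template consensus and voxel-wise
    behaviour-correlation maps.  A synthetic DWI phantom generator with
    programmed regional anisotropy deficits and behaviour-coupled scores
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nortest,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
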