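Package: pseudomri
Title: Head-Shape-Driven Individualization of MRI Templates by Thin-Plate-Spline Warping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates a "pseudo-MRI" by warping a segmented template MRI
    (surfaces and volumes) to a subject's digitized head shape. Conditions
    MEG/EEG scalp digitization points (fiducial-plane filtering, robust
    outlier rejection, sagittal-mirror densification, farthest-point
    downsampling, stylus-standoff compensation), solves an adaptively
    regularized three-dimensional thin-plate-spline warp from template
    scalp to head shape, and applies it to all template surfaces and
    volumes. Includes a synthetic head-phantom generator for end-to-end
    validation, surface-congruence metrics, and readers/writers for
    FreeSurfer binary surfaces, Wavefront OBJ, NIfTI-1 volumes and
    head-point files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
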