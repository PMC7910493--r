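Package: dhikit
Title: Diffusion Histology Imaging of Brain Tumor Microstructure
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for diffusion histology imaging (DHI) of high-grade
    brain tumors. Implements the diffusion basis spectrum imaging (DBSI)
    multi-tensor signal model with an isotropic diffusivity spectrum:
    forward signal prediction, voxel-wise inverse fitting by regularized
    non-negative least squares with orientation selection and nonlinear
    diffusivity refinement, and derivation of the twelve DTI/DBSI metrics
    used as classifier features. Includes synthetic phantoms (noisy
    diffusion-weighted volumes with known voxel composition and
    class-conditional feature tables), thin-plate-spline landmark
    registration for histology-to-MRI label transfer, SMOTE class
    balancing, a feed-forward neural network classifier of six tumor
    histology classes (batch normalization, exponential linear units,
    Adam), and an evaluation battery: confusion matrices, one-vs-rest
    ROC and precision-recall analysis, Youden operating points,
    F1 scores and percentile-bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    RNifti,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
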