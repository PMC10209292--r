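Package: mrept
Title: Phase-Based MREPT Conductivity Reconstruction and Repeatability
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs tissue electrical conductivity from the transceive
    phase of 3 T MRI scans using the phase-based magnetic resonance
    electrical properties tomography (MREPT) approximation
    sigma = laplacian(phi) / (2 mu0 omega). Provides a region-growing 3D
    phase unwrapper, an edge-preserving anisotropic diffusion filter, a
    tissue- and amplitude-restricted average parabolic-fit Laplacian
    estimator, and the repeatability statistics used to validate such
    measurements (ROI coefficient of variation, relative error,
    Bland-Altman limits of agreement, paired TOST equivalence testing with
    Monte-Carlo power, repeated-measures ANOVA). A discrete-Poisson forward
    simulator generates saline-phantom and brain-like synthetic datasets,
    with complex noise and compressed-sensing style degradation, so the
    whole pipeline can be exercised without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
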