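Package: satucorr
Title: Detector Saturation Correction for Cone-Beam CT by Low-Dose Scan
    Combination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects detector saturation (overexposure) artifacts in
    circular-trajectory cone-beam CT by combining an automatic-exposure-control
    (AEC) scan with an additional low-dose scan.  Saturated and background
    pixels are identified per projection by histogram-based thresholding, the
    masked low-dose pixels are scaled row-wise for a smooth seam and merged
    with the AEC projections on the lateral view range, and the combined
    projections are reconstructed with an FDK pipeline (cosine weighting,
    Parker short-scan weights, truncation correction, Shepp-Logan ramp
    filtering).  Inter-scan subject motion is compensated by a 3D non-rigid
    alignment: fiducial markers are tracked with the fast radial symmetry
    transform, localized in 3D by backprojection, and drive an affine
    moving-least-squares deformation applied during backprojection, after
    which the deformed volume is forward-projected to synthesize registered
    low-dose projections.  A polychromatic X-ray scan simulator with a
    parametric two-leg knee phantom, detector saturation, photon starvation
    and 14-bit quantization generates reference, overexposed and low-dose
    scan triples for end-to-end validation with SSIM and nRMSE volume
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
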