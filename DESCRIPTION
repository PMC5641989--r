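Package: ktqa
Title: Accelerated Phase-Contrast Cine MRI Analysis for Local Pulse Wave Velocity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring local pulse wave velocity (PWV) from
    phase-contrast cine cardiovascular MR images using the flow-area (QA)
    method. Implements lattice k-t undersampling with x-f space unfolding
    (k-t BLAST) for accelerated acquisitions, voxel-wise velocity fitting
    from multi-point flow encoding with goodness-of-fit exclusion,
    semi-automatic lumen segmentation by minimising the inter-encoding
    variance of thresholded pixel counts, and early-systolic Q(A) slope
    fitting. Includes a synthetic pulsatile-vessel phantom with known
    ground-truth PWV for end-to-end validation, plus Bland-Altman,
    regression-concordance and paired-t agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
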