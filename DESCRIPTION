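Package: kurtosig
Title: Glioma Diffusion-Signature Detection from Diffusion Kurtosis Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates mean-diffusivity (MD) and mean-kurtosis (MK) parametric
    maps from multi-shell diffusion-weighted MRI using the diffusion-kurtosis
    signal representation, builds the joint MK-MD occupancy of healthy brain
    from a reference cohort, labels voxels whose MK-MD combination falls
    outside that occupancy (the glioma "diffusion signature"), and evaluates
    the resulting automatic segmentation against a reference mask with the
    Dice coefficient.  Includes a synthetic multi-shell DWI phantom generator
    with Rician noise so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    yaml,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
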