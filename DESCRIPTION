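Package: conebeam
Title: Cone-Beam CT Reconstruction and Mutual-Information Non-Local
    Total-Variation Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for low-dose cone-beam computed tomography (CBCT) image
    formation and restoration. Provides a Siddon ray tracer with ray-driven
    and pixel-driven (FDK-style) backprojectors, Shepp-Logan/Hann ramp
    filtering with Parker short-scan weighting, a mutual-information-weighted
    non-local total-variation denoiser minimised by normalised gradient
    descent with adaptive step control, a Catphan-like digital phantom
    simulator with a Poisson low-dose noise model, and standard image-quality
    metrics (contrast-to-noise ratio, root-mean-square error, spatial
    non-uniformity, noise power spectrum, and intensity projections).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
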