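Package: mcdenoise
Title: Adaptive Nonlocal Means Denoising of 3-D Monte Carlo Photon Fluence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Denoises volumetric photon-fluence images produced by Monte Carlo
    photon-transport simulations using a spatially adaptive nonlocal means
    (ANLM) filter with patch preselection, per-voxel noise-variance
    estimation, Gaussian and Rician noise models, and wavelet sub-band mixing
    of two patch sizes. Includes a minimal voxel Monte Carlo photon simulator
    and an analytic diffusion surrogate with Poisson shot noise for
    generating realistic test volumes, plus repeated-realization
    signal-to-noise-ratio metrics and the filter-equivalent photon
    multiplier. Reads and writes headerless little-endian float32 volumes
    and NIfTI-1 images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
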