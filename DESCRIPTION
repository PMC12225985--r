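Package: dotae
Title: Adversarial Autoencoder Reconstruction for Ultrasound-Guided Diffuse
    Optical Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency-domain diffuse optical tomography (DOT) reconstruction
    for ultrasound-guided breast imaging. Provides a Born-approximation photon
    diffusion forward model for a semi-infinite medium, calibration of
    background optical properties from reference-side measurements, a
    Tikhonov-regularized conjugate-gradient baseline reconstruction, a
    synthetic lesion and measurement generator, and a hybrid
    autoencoder-adversarial reconstruction model in which an inverse operator
    (attention/residual encoder-decoder) and a forward operator are trained
    jointly with supervised perturbation-to-perturbation and adversarial
    reconstruction-to-reconstruction sequences. Evaluation utilities quantify
    maximum absorption coefficient and 50 percent-contour lesion diameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite,
    rhdf5,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
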