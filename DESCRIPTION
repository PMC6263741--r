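Package: dlpr
Title: Dictionary Learning Phase Retrieval from Noisy Coded Diffraction
    Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers complex-valued object wavefronts from the intensities of
    coded diffraction patterns corrupted by Poissonian (photon-limited) or
    Gaussian sensor noise. Implements an alternating-minimization phase
    retrieval engine with proximal sensor-plane filtering, complex-domain
    patch sparse coding by orthogonal matching pursuit, online complex-domain
    dictionary learning, a class-specific variant that plugs in a dictionary
    pre-trained on clean images, and a Gerchberg-Saxton style baseline with
    sensor filtering only. Includes the coded-diffraction acquisition
    simulator, synthetic phase-surface generators, wrapped-phase error
    metrics, and experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
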