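Package: echosim
Title: Pulse-Echo Ultrasound Imaging Simulation with Aperture Quadrature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates linear-array pulse-echo ultrasound imaging from first
    principles. Transmit and receive transient pressure fields at point
    scatterers are computed by Gauss-Legendre quadrature of the Rayleigh
    integral with analytic time evaluation, and received radio-frequency (RF)
    channel data is synthesized for synthetic aperture, focused B-mode, and
    steered plane wave transmissions. Includes delay-and-sum beamforming with
    a constant f-number and coherent compounding, Hilbert-envelope detection
    and log compression, seeded speckle phantom generators (cyst/point-target,
    grayscale-image template, and moving-scatterer vessel flow phantoms), a
    lag-one autocorrelation color Doppler velocity estimator with wall
    filtering and spatial smoothing, and a convergence harness comparing
    delay-handling strategies against a dense-discretization reference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    pracma,
    signal,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
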