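Package: perimem
Title: Peridynamic Simulation of Spontaneous Rupture in Supported Lipid
    Bilayer Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meshfree state-based peridynamic simulation of rupture in the
    distal bilayer of a supported double lipid bilayer membrane. Builds a
    circular particle lattice with a finite-horizon bond network, drives it
    with a radially expanding boundary layer, breaks bonds at a critical
    stretch, and integrates the equation of motion with the implicit
    trapezoidal rule under adaptive time-step control with mass scaling.
    Pinning sites (fixed particles) act as rupture nucleation sites; with
    increasing shear modulus the rupture morphology shifts from floral to
    fractal. Includes rasterisation of rupture contours, pore detection,
    and box-counting fractal-dimension analysis of the resulting patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mgcv,
    png,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
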