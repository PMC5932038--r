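Package: permeon
Title: Ion-Channel Permeation Analysis from Umbrella Sampling and
    Applied-Voltage Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs one-dimensional potentials of mean force from
    umbrella-sampling windows by the weighted histogram analysis method
    (WHAM), including cyclic profiles on periodic reaction coordinates and
    window-level bootstrap errors; converts bulk-referenced profiles into
    standard free energies of binding with an effective sampled-area
    correction from the covariance eigenvalues of the in-plane ion
    positions; counts periodic-boundary crossings in applied-field
    permeation trajectories, converts them to ionic currents and fits the
    current-voltage relation to report conductance; classifies ion exit
    pathways (central axial, cleft-then-axial, lateral) in cylindrical
    coordinates; and profiles hydration-shell counts and pore radii along
    a channel axis.  A Brownian-dynamics generator produces synthetic
    umbrella and permeation data with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
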