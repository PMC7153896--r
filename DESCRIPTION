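Package: microlane
Title: Cellular Potts Simulation and Trajectory Analysis of Cell Migration
    on Microlanes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates single cells confined to stripe-shaped adhesive
    micropatterns ("microlanes") with an extended Cellular Potts model in
    which a self-reinforcing polarization field couples protrusion and
    retraction events to cell polarity, producing quasi-periodic
    pole-to-pole migration. Provides the matching trajectory
    quantification pipeline: spatial occupancy and mean-speed profiles
    with change-point estimation of the repolarization zone, velocity
    distributions, ensemble Fourier spectra with log-normal peak fits,
    period-versus-lane-length regression, and reversal-time statistics.
    Includes lane geometry construction for four tip shapes at matched
    area, a synthetic trajectory generator with known ground truth for
    pipeline validation, and readers and writers for the plain-text
    trajectory table dialect used by micropattern tracking experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
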