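Package: pentasans
Title: Small-Angle Neutron Scattering Analysis of Pentameric Ion Channel
    Conformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and analysis of small-angle neutron scattering
    (SANS) from membrane proteins measured in D2O with match-out deuterated
    detergent. Computes theoretical scattering curves from atomic models via
    the Debye equation with hydrogen-deuterium exchange of labile hydrogens
    and shielding of transmembrane hydrogens, performs experimental-curve
    reduction (detector-distance merging, background subtraction,
    concentration normalisation), Guinier analysis and I(0)-based molecular
    weight estimation, regularised indirect Fourier transform of pair-distance
    distributions, single-structure and two-state mixture fitting by reduced
    chi-square, elastic-network interpolation of closed-to-open transition
    pathways, and principal-component landscapes correlating goodness of fit
    with collective motions. Includes a synthetic-data module generating toy
    pentameric channels and simulated two-detector-distance experiments with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
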