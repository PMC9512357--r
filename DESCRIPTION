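Package: vsmDose
Title: Virtual-Source Phase-Space Model and Voxel Monte Carlo Photon Dose Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dual-source virtual phase-space model of a 6 MV linear accelerator
    head (flattened and flattening filter-free beam qualities) with an
    Elekta-style 160-leaf multileaf collimator, coupled to a simplified
    voxel Monte Carlo photon dose engine. Builds calibrated fluence maps at
    the phase-space plane from tabulated source, profile, spectrum and
    collimator scatter parameters, samples particle records by rejection
    sampling, transports photons through voxel phantoms with Woodcock
    tracking (Compton, photoelectric and pair interactions; straight-line
    continuous-slowing-down electrons), and evaluates dose distributions via
    output factors, dose profiles and gamma index pass rates. Includes
    fixture generators for square, off-axis and toy step-and-shoot IMRT
    fields on synthetic phantoms, plus structured-text plan and dose I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
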