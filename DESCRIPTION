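Package: ctdosim
Title: Monte Carlo Dosimetry Model for Wide-Beam CT Scanners
Version: 0.1.0
Authors@R: person("ctdosim", "maintainers", email = "ctdosim@example.org",
    role = c("aut", "cre"))
Description: A self-contained simulator of wide-beam computed tomography (CT)
    scanner dosimetry. Characterizes the x-ray source from measurements
    (filtered energy spectrum with equivalent carbon/aluminum filtration,
    bowtie filter thickness profile, z-axis beam profile with heel effect),
    samples axial, helical and tube-current-modulated acquisitions along the
    gantry trajectory, converts CT Hounsfield units to voxel densities and
    elemental compositions through a stoichiometric calibration, and transports
    photons through the voxel phantom with Woodcock delta tracking under the
    kerma approximation. Provides air-kerma and half-value-layer computation,
    CTDI phantom fixtures, energy-deposition and track-length energy-fluence
    tallies with batch statistics, and dose reporting with CTDI and table
    attenuation correction factors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
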