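Package: holoRI
Title: Off-Axis Digital Holographic Microscopy Simulation and
    Refractive-Index Reconstruction
Version: 0.1.0
Authors@R:
    person("holoRI", "Developers", email = "holori@example.org",
           role = c("aut", "cre"))
Description: Simulates off-axis digital holograms of embryo-like spherical
    phase phantoms (multi-compartment specimens with a zona shell and an
    optional blastocoel cavity), recovers the wrapped object phase by
    Fourier sideband demodulation, unwraps it with the Herraez
    reliability-sorting algorithm, and converts phase to per-pixel
    effective refractive-index maps through a hemispherical chord model
    with annular background subtraction.  Includes the group-comparison
    statistics (normality-gated t/Mann-Whitney, one-way ANOVA with Tukey
    HSD), radius and background sensitivity analyses, dosimetry
    arithmetic, TIFF input/output and command-line entry points, so the
    full analysis chain is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
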