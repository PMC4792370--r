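Package: ionplasm
Title: Ionic Plasmons in Finite Spherical Electrolyte Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Random-phase-approximation (RPA) effective-jellium model of
    collective ion-density oscillations (ionic plasmons) in a finite spherical
    electrolyte bounded by an insulating membrane. Computes surface and volume
    plasmon self-frequencies (including spherical-Bessel radial modes and their
    temperature dependence), charge-density fluctuation fields, size-dependent
    attenuation from boundary/bulk ion scattering and Lorentz-friction radiation
    losses, the exact radiation-damped dipole dynamics via the cubic
    characteristic equation, driven time-domain dipole evolution, and the
    characteristic radii of minimal and maximal damping. Ships two canonical
    electrolyte presets and a command-line interface for parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    deSolve,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
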