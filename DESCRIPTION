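Package: ehgcv
Title: Conduction Velocity Analysis of the Electrohysterogram
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of uterine electrical activity recorded with a
    high-density surface electrode grid. Detects contractions from an estimated
    intrauterine pressure signal derived from the bipolar electrohysterogram via
    the unnormalized first spectral moment in the 0.3-0.8 Hz band, estimates the
    two-dimensional conduction-velocity vector of propagating action potentials
    by frequency-domain maximum-likelihood delay estimation over the electrode
    grid under a plane-wave model, excludes supra-physiological velocities, and
    compares per-patient mean conduction velocities between labor and nonlabor
    groups. Includes a plane-wave simulator with known ground truth, a minimal
    EDF reader/writer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
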