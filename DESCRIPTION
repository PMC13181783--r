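Package: hdospec
Title: Vibrational Spectral Diffusion Observables for Water Force-Field
    Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the vibrational observables of an HDO probe molecule
    embedded in liquid water sampled by molecular dynamics: solvation-shell
    clusters are carved around the probe using radial-distribution-function
    cutoffs, per-snapshot harmonic frequencies of the three HDO modes (HOD
    bend, OD stretch, OH stretch) are obtained through a pluggable frequency
    engine, and the resulting mode series are reduced to central frequencies,
    fluctuation amplitudes, coordination-resolved subdistributions, and
    spectral-diffusion times from biexponential fits of the
    frequency-fluctuation correlation function. Includes Kubo-process and
    water-box simulators with known statistics, and a benchmark module that
    reports percent differences of each force field against a reference
    potential.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
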