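Package: sgld
Title: Self-Guided Molecular and Langevin Dynamics Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enhanced-sampling molecular simulation via self-guided molecular
    dynamics (SGMD) and self-guided Langevin dynamics (SGLD). Guiding forces are
    built from exponential local averages of past momenta and forces so that
    low-frequency motion is promoted without raising the temperature. Includes
    the generalized leap-frog integrator with on-the-fly apparent-friction
    estimation and an energy-conservation scaling factor, canonical-ensemble
    reweighting of self-guided trajectories, a colored-noise variant derived
    from the generalized Langevin equation (SGLD-GLE) that preserves the
    canonical ensemble exactly, and replica-exchanging SGLD (RXSGLD) over
    ladders of guiding parameters. Ships fully parameterized toy systems (a
    skewed double-well particle and Lennard-Jones argon) plus trajectory
    analysis tools: velocity autocorrelation power spectra, diffusion
    constants, barrier-crossing counts and energy histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
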