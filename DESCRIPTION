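Package: stochanest
Title: Stochastic State-Switching Analysis of Anesthetic Responsiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing trial-to-trial fluctuations in binary
    behavioral responsiveness under fixed anesthetic concentrations.
    Fits two-state Markov chains to righting-reflex and startle-reflex
    trial series, compares them against a memoryless Bernoulli null,
    characterises structured inter-individual variability in the plane
    of the transition-matrix diagonals (PCA, diagonal correlation,
    permutation tests of individual stability), decodes drug
    concentration from individual responsiveness by Bayesian inversion
    of bootstrap response-probability densities, fits constrained Hill
    dose-response curves on jackknifed subsamples, and simulates a
    noise-driven bistable neuronal network as diffusion on a two-well
    energy landscape. Includes a synthetic-cohort generator emulating
    the mouse and larval-zebrafish study designs so the full pipeline
    is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
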