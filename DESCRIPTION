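Package: cvident
Title: Practical Identifiability Analysis for a Multiscale Biventricular
    Cardiovascular Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a multiscale lumped-parameter cardiovascular model
    coupling sarcomere-level stress generation, a three-segment (TriSeg)
    model of biventricular interaction, and a zero-dimensional systemic and
    pulmonary circulation, calibrated to normotensive mouse hemodynamics.
    Provides the full in-silico experimental-design workflow around the
    model: synthetic pressure/volume data generation under four measurement
    protocols, Morris elementary-effects screening, local sensitivity and
    Fisher-information/SVD parameter-subset selection, profile-likelihood
    identifiability classification, delayed-rejection adaptive-Metropolis
    (DRAM) Markov chain Monte Carlo with Gelman-Rubin diagnostics, and
    posterior-predictive forecasting of pulmonary-hypertension biomarkers
    such as end-systolic elastance and ventricular-vascular coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
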