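Package: oscillab
Title: Hopf Bifurcation Analysis of Genetic Negative-Feedback Oscillators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Locates Hopf bifurcation values of single-cell and coupled-cell
    genetic negative-feedback (Goodwin-type) oscillators via a degenerate
    Routh-Hurwitz criterion, traces complex eigenvalue branches between
    single-cell and coupled-cell bifurcation points, extracts limit-cycle
    periods, frequencies, amplitudes and phase differences by high-accuracy
    simulation, computes Hopf normal-form coefficients to classify the
    bifurcation, and compares the collective frequency of coupled cells with
    the average of the individual frequencies for Hill-type versus
    protein-sequestration repression. Includes a segmentation-clock pair model
    for cross-system comparison and a registry of reference parameter sets.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
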