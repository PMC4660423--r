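Package: biphasicCI
Title: Two-Dimensional Loewe Additivity and Combination Indices for
    Biphasic Dose-Response Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits inverted v-shaped (biphasic) dose-response curves of
    inducible whole-cell biosensors with split Gaussian and log-Gaussian
    peak models, optionally with a Box-Cox transform-both-sides variance
    stabilisation.  Extends the effective dose to a two-dimensional vector
    EDp = (D(p), E(p)) over a fractional-effect scale p in (-100, 100)
    spanning both the induction and the inhibition branch, predicts
    additive mixture responses under a two-dimensional formulation of
    Loewe additivity (concentration addition), and quantifies departures
    from additivity through dose- and effect-dimension combination
    indices CI_D and CI_E, the weighted index CI_w = CI_D * CI_E, and a
    replicate-level t-test, with synergism/additive/antagonism
    classification for risk management.  Includes a synthetic-data module
    (serial-dilution designs, constant-ratio mixture rays, multiplicative
    noise) so the full pipeline is testable without laboratory data.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
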