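Package: discratchet
Title: Ratcheting Analysis of Intervertebral Discs Under Cyclic Compression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the ratcheting (progressive mean-strain
    accumulation) of intervertebral discs under stress-controlled uniaxial
    cyclic compression. Provides a synthetic generator for triangular-wave
    cyclic-compression test records, per-cycle hysteresis-loop metrics
    (ratcheting strain, ratcheting strain rate, strain range, compression
    stiffness), nonlinear least-squares fitting of a one-parameter saturating
    ratcheting evolution model with a material coefficient, linear
    parameter-stress relations for the evolution parameters, prediction of
    ratcheting strain evolution at unseen stress levels, and a statistical
    reporting layer (Pearson correlation, one-way ANOVA, directional effect
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
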