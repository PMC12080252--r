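Package: daphtk
Title: Chronic Toxicity and Bioaccumulation Assessment for Daphnia magna
    Under Passive Dosing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for chronic toxicity and bioaccumulation
    assessment of hydrophobic chemicals in Daphnia magna under passive
    dosing. Provides exposure-stability quality control across media-change
    cycles, OECD-211 reproduction-test analysis with four-parameter logistic
    dose-response fitting and bootstrap ECx confidence intervals, chemical
    activity and critical target lipid body burden computations,
    one-compartment depuration kinetics with growth-dilution correction,
    kinetic bioaccumulation factors with lipid normalization, derivation of
    organism-specific depuration-rate thresholds for bioaccumulative and
    very-bioaccumulative (B/vB) classification, PNEC and risk-quotient
    screening, and seeded synthetic-data generators so every pipeline stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
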