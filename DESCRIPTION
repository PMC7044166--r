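Package: pkddi
Title: Bioanalytical Calibration, Method Validation and Non-Compartmental
    Drug-Drug Interaction Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("pkddi", "developers", email = "pkddi@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for LC-MS/MS pharmacokinetic drug-drug
    interaction studies in small animals: least-squares calibration curves
    with full regression statistics and back-calculation, FDA-style
    bioanalytical validation metrics (accuracy, precision, extraction
    recovery, matrix effect, selectivity, carryover, stability, dilution
    integrity) with acceptance verdicts, non-compartmental analysis of
    concentration-time profiles (Cmax, tmax, terminal elimination rate,
    half-life, trapezoidal AUC with extrapolation, apparent clearance),
    and group-level interaction statistics (relative bioavailability,
    metabolite/parent ratio, two-sample t-tests).  Includes a seeded
    one-compartment parent/metabolite study simulator so every stage is
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
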