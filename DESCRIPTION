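Package: protaff
Title: Conformer Mapping and Benchmark Thermochemistry for Amino-Acid
    Protonation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for computing gas-phase proton affinities
    and basicities of flexible molecules from conformer ensembles.
    Implements symmetry-reduced torsional grid enumeration, conformer
    deduplication by relative energy and rotational constant, focal-point
    composite energy assembly from per-conformer correction ledgers,
    rigid-rotor harmonic-oscillator statistical thermodynamics, and
    Boltzmann-mixture proton affinity and gas-phase basicity evaluation.
    Ships an analytic torsional toy potential and a synthetic ledger
    generator so the full workflow runs without any electronic-structure
    software, plus transcriptions of published cysteine benchmark tables
    as fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
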