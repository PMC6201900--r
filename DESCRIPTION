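Package: kinensemble
Title: Ensembles of Kinetic Parameters for Metabolic Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Samples random mass-action rate constants for metabolic
    networks, integrates the resulting ordinary differential equations to
    a quantified steady state, back-calculates reaction fluxes from the
    steady-state concentrations, and filters parametrizations into
    phenotype ensembles defined by flux-sign predicates derived from flux
    balance analysis.  Populated ensembles are characterized through
    per-reaction median and dispersion summaries and pairwise two-sample
    Kolmogorov-Smirnov tests that identify fluxes discriminating every
    pair of growth conditions.  Includes an SBML and tabular model
    reader, reversible-reaction splitting, an HDF5 experiment store, and
    synthetic fixture generators with closed-form steady states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    magrittr,
    purrr,
    readr,
    rhdf5,
    rlang (>= 1.0.0),
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
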