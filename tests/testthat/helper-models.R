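# Shared in-code fixtures for the test suite.

# A tiny SBML document: two compartments (cytosol c, external e), one
# boundary species, one reversible and two irreversible reactions.
sbml_fixture_text <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">\n',
    '<model id="toy">\n',
    '<listOfCompartments>\n',
    '<compartment id="c"/><compartment id="e"/>\n',
    '</listOfCompartments>\n',
    '<listOfSpecies>\n',
    '<species id="glc_e" compartment="e" initialConcentration="5" boundaryCondition="true"/>\n',
    '<species id="glc_c" compartment="c" initialConcentration="1"/>\n',
    '<species id="pyr_c" compartment="c" initialConcentration="0.5"/>\n',
    '<species id="pyr_e" compartment="e" initialConcentration="0"/>\n',
    '</listOfSpecies>\n',
    '<listOfReactions>\n',
    '<reaction id="Upt" reversible="false">\n',
    '<listOfReactants><speciesReference species="glc_e"/></listOfReactants>\n',
    '<listOfProducts><speciesReference species="glc_c"/></listOfProducts>\n',
    '</reaction>\n',
    '<reaction id="PGM" reversible="true">\n',
    '<listOfReactants><speciesReference species="glc_c" stoichiometry="1"/></listOfReactants>\n',
    '<listOfProducts><speciesReference species="pyr_c" stoichiometry="2"/></listOfProducts>\n',
    '</reaction>\n',
    '<reaction id="Exp" reversible="false">\n',
    '<listOfReactants><speciesReference species="pyr_c"/></listOfReactants>\n',
    '<listOfProducts><speciesReference species="pyr_e"/></listOfProducts>\n',
    '</reaction>\n',
    '</listOfReactions>\n',
    '</model>\n</sbml>\n'
  )
}

write_sbml_fixture <- function(path = tempfile(fileext = ".xml")) {
  writeLines(sbml_fixture_text(), path)
  path
}

# Random small model with a mix of reversible and irreversible reactions.
random_model <- function(seed, n_species = 4, n_irr = 3, n_rev = 2) {
  set.seed(seed)
  sp <- paste0("S", seq_len(n_species))
  mk <- function(i, rev) {
    from <- sample(sp, 1)
    to <- sample(setdiff(sp, from), 1)
    tibble::tibble(id = paste0(if (rev) "V" else "R", i), reversible = rev,
                   reactants = list(stats::setNames(sample(1:2, 1), from)),
                   products = list(stats::setNames(sample(1:2, 1), to)))
  }
  rx <- dplyr::bind_rows(
    lapply(seq_len(n_irr), mk, rev = FALSE),
    if (n_rev > 0) dplyr::bind_rows(lapply(seq_len(n_rev), mk, rev = TRUE))
  )
  metabolic_model(tibble::tibble(id = sp, initial_concentration = 1), rx)
}

# Wide one-row flux record over the marker reactions.
marker_record <- function(values = list()) {
  markers <- unique(builtin_filters()$reaction_id)
  v <- stats::setNames(rep(0, length(markers)), markers)
  for (nm in names(values)) v[[nm]] <- values[[nm]]
  tibble::as_tibble(as.list(v))
}
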