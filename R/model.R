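#' Construct a metabolic model
#'
#' A metabolic model bundles an ordered species table and an ordered
#' reaction table.  Species carry an initial concentration (assumed mM), a
#' `clamped` flag (held constant during simulation, e.g. boundary nutrients
#' and ions) and an `internal` flag (evaluated by the steady-state
#' criterion).  Reactions are stored with separate reactant and product
#' coefficient maps; after [split_reversible()] every reaction is
#' irreversible and mass-action kinetic orders equal the reactant-side
#' stoichiometric coefficients.
#'
#' @param species A data frame with at least a column `id`.  Optional
#'   columns: `name`, `compartment`, `internal` (logical, default `TRUE`),
#'   `clamped` (logical, default `FALSE`), `initial_concentration`
#'   (non-negative, default 0).
#' @param reactions A data frame with columns `id`, `reversible` (logical)
#'   and list-columns `reactants` and `products`, each entry a named
#'   numeric vector of positive stoichiometric coefficients (possibly
#'   empty for pure exchange reactions).
#' @return An object of class `metabolic_model`.
#' @examples
#' m <- metabolic_model(
#'   species = tibble::tibble(id = c("A", "B")),
#'   reactions = tibble::tibble(
#'     id = "R1", reversible = FALSE,
#'     reactants = list(c(A = 1)), products = list(c(B = 1))
#'   )
#' )
#' m
#' @export
metabolic_model <- function(species, reactions) {
  species <- as_tibble(species)
  reactions <- as_tibble(reactions)
  if (nrow(species) == 0L || nrow(reactions) == 0L) {
    abort("A metabolic model needs at least one species and one reaction.",
          class = "kin_validation_error")
  }
  if (!"id" %in% names(species)) {
    abort("`species` must have an `id` column.", class = "kin_validation_error")
  }
  if (!all(c("id", "reversible", "reactants", "products") %in% names(reactions))) {
    abort("`reactions` must have columns id, reversible, reactants, products.",
          class = "kin_validation_error")
  }
  if (!"name" %in% names(species)) species$name <- species$id
  if (!"compartment" %in% names(species)) species$compartment <- NA_character_
  if (!"internal" %in% names(species)) species$internal <- TRUE
  if (!"clamped" %in% names(species)) species$clamped <- FALSE
  if (!"initial_concentration" %in% names(species)) {
    species$initial_concentration <- 0
  }
  species <- species[, c("id", "name", "compartment", "internal", "clamped",
                         "initial_concentration")]
  model <- structure(list(species = species, reactions = reactions),
                     class = "metabolic_model")
  validate_model(model)
}

validate_model <- function(model) {
  sp <- model$species
  rx <- model$reactions
  if (anyDuplicated(sp$id)) {
    abort(paste0("Duplicate species id: ",
                 paste(unique(sp$id[duplicated(sp$id)]), collapse = ", ")),
          class = "kin_validation_error")
  }
  if (anyDuplicated(rx$id)) {
    abort(paste0("Duplicate reaction id: ",
                 paste(unique(rx$id[duplicated(rx$id)]), collapse = ", ")),
          class = "kin_validation_error")
  }
  if (any(sp$initial_concentration < 0)) {
    abort("Initial concentrations must be non-negative.",
          class = "kin_validation_error")
  }
  for (i in seq_len(nrow(rx))) {
    re <- rx$reactants[[i]]
    pr <- rx$products[[i]]
    if (length(re) == 0L && length(pr) == 0L) {
      abort(paste0("Reaction '", rx$id[i], "' has empty reactant and product sides."),
            class = "kin_validation_error")
    }
    refs <- c(names(re), names(pr))
    unknown <- setdiff(refs, sp$id)
    if (length(unknown)) {
      abort(paste0("Reaction '", rx$id[i], "' references unknown species: ",
                   paste(unknown, collapse = ", ")),
            class = "kin_validation_error")
    }
    if (any(c(re, pr) <= 0)) {
      abort(paste0("Reaction '", rx$id[i], "' has non-positive stoichiometric coefficients."),
            class = "kin_validation_error")
    }
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  n_rev <- sum(x$reactions$reversible)
  cat("<metabolic_model> ", nrow(x$species), " species (",
      sum(x$species$internal), " internal, ", sum(x$species$clamped),
      " clamped), ", nrow(x$reactions), " reactions (", n_rev,
      " reversible)\n", sep = "")
  invisible(x)
}

#' Number of species / reactions of a model
#' @param model A `metabolic_model`.
#' @return An integer scalar.
#' @export
n_species <- function(model) nrow(model$species)

#' @rdname n_species
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' Parse a reaction equation string
#'
#' The tabular model dialect writes one reaction per line as e.g.
#' `"2 A + B -> C"`; `"<->"` marks a reversible reaction and either side
#' may be empty for exchange reactions (`"A ->"` drains A, `"-> A"`
#' supplies it).
#'
#' @param equation A single equation string.
#' @return A list with elements `reactants`, `products` (named numeric
#'   vectors) and `reversible` (logical).
#' @export
parse_equation <- function(equation) {
  stopifnot(is.character(equation), length(equation) == 1L)
  reversible <- grepl("<->", equation, fixed = TRUE)
  sides <- if (reversible) {
    strsplit(equation, "<->", fixed = TRUE)[[1]]
  } else {
    if (!grepl("->", equation, fixed = TRUE)) {
      abort(paste0("Cannot parse equation (no '->'): '", equation, "'"),
            class = "kin_parse_error")
    }
    strsplit(equation, "->", fixed = TRUE)[[1]]
  }
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(s) {
    s <- trimws(s)
    if (s == "") return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (term in terms) {
      m <- regmatches(term, regexec("^([0-9]*\\.?[0-9]+\\s+)?(\\S+)$", term))[[1]]
      if (length(m) == 0L) {
        abort(paste0("Cannot parse equation term: '", term, "'"),
              class = "kin_parse_error")
      }
      coef <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
      id <- m[3]
      out[id] <- if (id %in% names(out)) out[[id]] + coef else coef
    }
    out
  }
  list(reactants = parse_side(sides[1]),
       products = parse_side(sides[2]),
       reversible = reversible)
}

format_equation <- function(reactants, products, reversible) {
  fmt_side <- function(v) {
    if (length(v) == 0L) return("")
    paste(ifelse(v == 1, names(v),
                 paste(format(v, trim = TRUE, scientific = FALSE), names(v))),
          collapse = " + ")
  }
  paste(fmt_side(reactants), if (reversible) "<->" else "->", fmt_side(products))
}

#' Read / write a model in the tabular reaction dialect
#'
#' A TSV with columns `reaction_id` and `equation`, one reaction per line.
#' Species are collected from the equations; flags and concentrations can
#' be attached afterwards with [set_concentrations()].
#'
#' @param path Path to a TSV file (or, for `read_reaction_table`, a
#'   literal character vector of lines).
#' @return `read_reaction_table()` returns a `metabolic_model`;
#'   `write_reaction_table()` invisibly returns `path`.
#' @export
read_reaction_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("reaction_id", "equation") %in% names(tbl))) {
    abort("Reaction table needs columns `reaction_id` and `equation`.",
          class = "kin_parse_error")
  }
  parsed <- map(tbl$equation, parse_equation)
  reactions <- tibble(
    id = tbl$reaction_id,
    reversible = map_lgl(parsed, "reversible"),
    reactants = map(parsed, "reactants"),
    products = map(parsed, "products")
  )
  ids <- unique(unlist(map(parsed, ~ c(names(.x$reactants), names(.x$products)))))
  metabolic_model(species = tibble(id = ids), reactions = reactions)
}

#' @rdname read_reaction_table
#' @param model A `metabolic_model`.
#' @export
write_reaction_table <- function(model, path) {
  tbl <- tibble(
    reaction_id = model$reactions$id,
    equation = pmap(list(model$reactions$reactants, model$reactions$products,
                         model$reactions$reversible), format_equation) |>
      unlist()
  )
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read a metabolic model from an SBML file
#'
#' A focused SBML Level 2/3 reader built on xml2, covering the subset the
#' mass-action framework needs: species (compartment, boundary condition,
#' initial concentration) and reactions (reversibility, stoichiometric
#' species references).  Species are flagged external when their SBML
#' `boundaryCondition` is true or their compartment is listed in
#' `external_compartments`.
#'
#' @param path Path to an SBML file.
#' @param external_compartments Compartment ids treated as extracellular;
#'   their species get `internal = FALSE`.
#' @return A `metabolic_model` with reversibility flags as declared.
#' @export
read_sbml_model <- function(path, external_compartments = c("e", "ext", "external")) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("Cannot parse SBML document: ", conditionMessage(e)),
          class = "kin_parse_error")
  })
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0L) {
    abort("SBML document contains no species.", class = "kin_parse_error")
  }
  attr_or <- function(nodes, attr, default) {
    v <- xml2::xml_attr(nodes, attr)
    ifelse(is.na(v), default, v)
  }
  boundary <- tolower(attr_or(sp_nodes, "boundaryCondition", "false")) == "true"
  compartment <- xml2::xml_attr(sp_nodes, "compartment")
  conc <- suppressWarnings(as.numeric(attr_or(sp_nodes, "initialConcentration", "0")))
  conc[is.na(conc)] <- 0
  species <- tibble(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = attr_or(sp_nodes, "name", xml2::xml_attr(sp_nodes, "id")),
    compartment = compartment,
    internal = !boundary & !(compartment %in% external_compartments),
    clamped = boundary,
    initial_concentration = conc
  )
  if (any(is.na(species$id))) {
    abort("SBML species element without an id attribute.", class = "kin_parse_error")
  }
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0L) {
    abort("SBML document contains no reactions.", class = "kin_parse_error")
  }
  read_side <- function(node, side) {
    refs <- xml2::xml_find_all(node, paste0("./", side, "/speciesReference"))
    if (length(refs) == 0L) return(stats::setNames(numeric(0), character(0)))
    st <- suppressWarnings(as.numeric(attr_or(refs, "stoichiometry", "1")))
    st[is.na(st)] <- 1
    stats::setNames(st, xml2::xml_attr(refs, "species"))
  }
  reactions <- tibble(
    id = xml2::xml_attr(rx_nodes, "id"),
    # SBML Level 2 defaults reversible to true when the attribute is absent
    reversible = tolower(attr_or(rx_nodes, "reversible", "true")) == "true",
    reactants = map(rx_nodes, read_side, side = "listOfReactants"),
    products = map(rx_nodes, read_side, side = "listOfProducts")
  )
  metabolic_model(species, reactions)
}

#' Load a metabolic model from SBML or the tabular dialect
#'
#' Dispatches on the file extension: `.xml`/`.sbml` goes to
#' [read_sbml_model()], anything else to [read_reaction_table()].
#'
#' @inheritParams read_sbml_model
#' @param ... Passed on to the format-specific reader.
#' @return A `metabolic_model`.
#' @export
load_model <- function(path, ...) {
  if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
    read_sbml_model(path, ...)
  } else {
    read_reaction_table(path, ...)
  }
}

#' Split reversible reactions into forward and backward copies
#'
#' Every reversible reaction is replaced by an irreversible forward copy
#' (same id) followed by a backward copy with the id suffixed
#' `"_reverse"` and reactants/products swapped.  Irreversible reactions
#' pass through unchanged, so the split model has
#' `n_irreversible + 2 * n_reversible` reactions.
#'
#' @param model A `metabolic_model`.
#' @return A fully irreversible `metabolic_model`.
#' @export
split_reversible <- function(model) {
  rx <- model$reactions
  rows <- map(seq_len(nrow(rx)), function(i) {
    r <- rx[i, ]
    if (!r$reversible) return(r)
    fwd <- r
    fwd$reversible <- FALSE
    bwd <- r
    bwd$id <- paste0(r$id, "_reverse")
    bwd$reversible <- FALSE
    bwd$reactants <- r$products
    bwd$products <- r$reactants
    bind_rows(fwd, bwd)
  })
  metabolic_model(model$species, bind_rows(rows))
}

#' Build stoichiometric and kinetic-order matrices
#'
#' `S` is the signed stoichiometric matrix (species in rows, reactions in
#' columns; products positive, reactants negative).  `A` holds the
#' reactant-side coefficients only and supplies the kinetic orders of the
#' mass-action rate law.  The model must already be irreversible (see
#' [split_reversible()]).
#'
#' @param model An irreversible `metabolic_model`.
#' @return A list with matrices `S` and `A`, both `n_species` by
#'   `n_reactions` with dimnames.
#' @export
build_matrices <- function(model) {
  if (any(model$reactions$reversible)) {
    abort("Model still contains reversible reactions; call split_reversible() first.",
          class = "kin_validation_error")
  }
  ns <- n_species(model)
  nr <- n_reactions(model)
  dn <- list(model$species$id, model$reactions$id)
  S <- matrix(0, ns, nr, dimnames = dn)
  A <- matrix(0, ns, nr, dimnames = dn)
  for (i in seq_len(nr)) {
    re <- model$reactions$reactants[[i]]
    pr <- model$reactions$products[[i]]
    if (length(re)) {
      S[names(re), i] <- S[names(re), i] - re
      A[names(re), i] <- A[names(re), i] + re
    }
    if (length(pr)) {
      S[names(pr), i] <- S[names(pr), i] + pr
    }
  }
  list(S = S, A = A)
}

#' Attach initial concentrations and clamped flags to a model
#'
#' Species listed in `concentrations` receive their value; species without
#' a listed value receive the mean of the listed values that matched the
#' model, mirroring the fallback used when a metabolome database lacks an
#' entry.  `clamped` ids are held constant during simulation.
#'
#' @param model A `metabolic_model`.
#' @param concentrations A named numeric vector or a data frame with
#'   columns `species_id` and `concentration` (units assumed mM).
#' @param clamped Character vector of species ids to clamp (or `NULL` to
#'   leave flags untouched).
#' @return The updated `metabolic_model`.
#' @export
set_concentrations <- function(model, concentrations, clamped = NULL) {
  if (is.data.frame(concentrations)) {
    if (!all(c("species_id", "concentration") %in% names(concentrations))) {
      abort("Concentration table needs columns `species_id` and `concentration`.",
            class = "kin_validation_error")
    }
    conc <- stats::setNames(as.numeric(concentrations$concentration),
                            concentrations$species_id)
  } else {
    conc <- concentrations
  }
  if (any(conc < 0)) {
    abort("Concentrations must be non-negative.", class = "kin_validation_error")
  }
  sp <- model$species
  listed <- intersect(names(conc), sp$id)
  if (length(listed) == 0L) {
    abort("No listed concentration matches a model species.",
          class = "kin_validation_error")
  }
  fallback <- mean(conc[listed])
  sp$initial_concentration <- ifelse(sp$id %in% listed,
                                     unname(conc[sp$id]), fallback)
  if (!is.null(clamped)) {
    missing <- setdiff(clamped, sp$id)
    if (length(missing)) {
      abort(paste0("Clamped ids absent from model: ",
                   paste(missing, collapse = ", ")),
            class = "kin_validation_error")
    }
    sp$clamped <- sp$id %in% clamped
  }
  metabolic_model(sp, model$reactions)
}

#' Read a concentration table or a clamped-species list from disk
#'
#' @param path TSV with columns `species_id`, `concentration` (for
#'   `read_concentration_table`) or a plain file with one species id per
#'   line (for `read_clamped_list`).
#' @return A tibble, respectively a character vector.
#' @export
read_concentration_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    species_id = readr::col_character(),
    concentration = readr::col_double()
  ))
  as_tibble(tbl)
}

#' @rdname read_concentration_table
#' @export
read_clamped_list <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}
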