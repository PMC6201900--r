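#' Built-in phenotype filters for the five E. coli growth conditions
#'
#' A phenotype filter is a conjunction of flux-sign predicates over
#' thresholded steady-state fluxes; a flux distribution belongs to a
#' phenotype iff every predicate holds.  The built-ins encode the five
#' growth conditions of the E. coli core case study:
#' * exp1 (aerobic, glucose): G6PDH2r > 0, GND > 0, PGL > 0,
#'   GLCptspp > 0, O2Up > 0
#' * exp2 (anaerobic, glucose): AcEx > 0, ALCD2x > 0, EthEx > 0,
#'   GLCptspp > 0, O2Up = 0
#' * exp3 (aerobic, acetate): MALS > 0, ICL > 0, AcUp > 0, O2Up > 0
#' * exp4 (aerobic, succinate): SUCCt2_2pp > 0, ME2 > 0, O2Up > 0
#' * exp5 (aerobic, glycerol): GLYK > 0, F6PA > 0, GLYCDx > 0, O2Up > 0
#'
#' @return A `phenotype_filters` tibble with columns `phenotype_id`,
#'   `reaction_id`, `comparator` (one of `"greater_than_zero"`,
#'   `"equal_zero"`).
#' @export
builtin_filters <- function() {
  gt <- "greater_than_zero"
  eq <- "equal_zero"
  tbl <- bind_rows(
    tibble(phenotype_id = "exp1",
           reaction_id = c("G6PDH2r", "GND", "PGL", "GLCptspp", "O2Up"),
           comparator = gt),
    tibble(phenotype_id = "exp2",
           reaction_id = c("AcEx", "ALCD2x", "EthEx", "GLCptspp", "O2Up"),
           comparator = c(gt, gt, gt, gt, eq)),
    tibble(phenotype_id = "exp3",
           reaction_id = c("MALS", "ICL", "AcUp", "O2Up"),
           comparator = gt),
    tibble(phenotype_id = "exp4",
           reaction_id = c("SUCCt2_2pp", "ME2", "O2Up"),
           comparator = gt),
    tibble(phenotype_id = "exp5",
           reaction_id = c("GLYK", "F6PA", "GLYCDx", "O2Up"),
           comparator = gt)
  )
  new_phenotype_filters(tbl)
}

new_phenotype_filters <- function(tbl) {
  tbl <- as_tibble(tbl)
  stopifnot(all(c("phenotype_id", "reaction_id", "comparator") %in% names(tbl)))
  if (nrow(tbl) == 0L) {
    abort("A filter set needs at least one predicate.",
          class = "kin_validation_error")
  }
  bad <- setdiff(unique(tbl$comparator), c("greater_than_zero", "equal_zero"))
  if (length(bad)) {
    abort(paste0("Unknown comparator(s): ", paste(bad, collapse = ", ")),
          class = "kin_validation_error")
  }
  class(tbl) <- c("phenotype_filters", class(tbl))
  tbl
}

#' Read / write phenotype filters as JSON
#'
#' The JSON layout is a list of objects
#' `{"phenotype": "exp5", "all_of": [{"flux": "GLYK", "op": ">", "value": 0}, ...]}`
#' where `op` is `">"` (greater than zero) or `"="` (equal zero).
#'
#' @param path JSON file path.
#' @return `read_filters_json()` returns a `phenotype_filters` tibble.
#' @export
read_filters_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- map(raw, function(ph) {
    tibble(
      phenotype_id = ph$phenotype,
      reaction_id = map_chr(ph$all_of, "flux"),
      comparator = map_chr(ph$all_of, function(p) {
        switch(p$op,
               ">" = "greater_than_zero",
               "=" = , "==" = "equal_zero",
               abort(paste0("Unknown predicate op '", p$op, "'"),
                     class = "kin_parse_error"))
      })
    )
  })
  new_phenotype_filters(bind_rows(rows))
}

#' @rdname read_filters_json
#' @param filters A `phenotype_filters` tibble.
#' @export
write_filters_json <- function(filters, path) {
  split_f <- split(as_tibble(filters), filters$phenotype_id)
  payload <- map(split_f, function(tbl) {
    list(
      phenotype = tbl$phenotype_id[[1]],
      all_of = pmap(list(tbl$reaction_id, tbl$comparator), function(r, cmp) {
        list(flux = r, op = if (cmp == "equal_zero") "=" else ">", value = 0)
      })
    )
  })
  jsonlite::write_json(unname(payload), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Assign flux records to phenotype ensembles
#'
#' Evaluates every filter on every record of a wide flux table.  A
#' phenotype membership is granted iff all of its predicates hold:
#' `greater_than_zero` means flux strictly positive after thresholding,
#' `equal_zero` means flux exactly zero after thresholding.  Records may
#' belong to zero, one, or several phenotypes.
#'
#' @param fluxes A data frame with one row per record and one numeric
#'   column per reaction (plus optional id columns such as
#'   `parametrization_id`, `condition_id`), already thresholded with
#'   [threshold_fluxes()].  A single `kin_fluxes` tibble (long, columns
#'   `reaction_id`/`flux`) is also accepted.
#' @param filters A `phenotype_filters` tibble, default
#'   [builtin_filters()].
#' @return A membership tibble: the id columns of `fluxes` plus one
#'   logical column per phenotype.
#' @export
assign_phenotypes <- function(fluxes, filters = builtin_filters()) {
  if (inherits(fluxes, "kin_fluxes")) {
    wide <- as_tibble(as.list(stats::setNames(fluxes$flux, fluxes$reaction_id)))
    wide$parametrization_id <- attr(fluxes, "parametrization_id")
    wide$condition_id <- attr(fluxes, "condition_id")
    fluxes <- wide
  }
  needed <- unique(filters$reaction_id)
  missing <- setdiff(needed, names(fluxes))
  if (length(missing)) {
    abort(paste0("Flux records lack reactions referenced by filters: ",
                 paste(missing, collapse = ", ")),
          class = "kin_validation_error")
  }
  id_cols <- intersect(c("record_id", "parametrization_id", "condition_id"),
                       names(fluxes))
  out <- fluxes[, id_cols, drop = FALSE]
  for (ph in unique(filters$phenotype_id)) {
    preds <- filters[filters$phenotype_id == ph, ]
    ok <- rep(TRUE, nrow(fluxes))
    for (j in seq_len(nrow(preds))) {
      v <- fluxes[[preds$reaction_id[j]]]
      ok <- ok & if (preds$comparator[j] == "greater_than_zero") v > 0 else v == 0
    }
    out[[ph]] <- ok
  }
  as_tibble(out)
}

#' Phenotype set of a single flux distribution
#'
#' @inheritParams assign_phenotypes
#' @return Character vector of satisfied phenotype ids.
#' @export
phenotype_set <- function(fluxes, filters = builtin_filters()) {
  m <- assign_phenotypes(fluxes, filters)
  ph <- unique(filters$phenotype_id)
  ph[vapply(ph, function(p) isTRUE(m[[p]][1]), logical(1))]
}

combo_label <- function(ids) {
  if (length(ids) == 0L) return("")
  paste(sort(sub("^exp", "", ids)), collapse = "")
}

#' Ensemble cardinality analysis
#'
#' Counts, for every subset of phenotypes, the records whose membership
#' set equals exactly that subset (e.g. combination `"12"` means exp1 and
#' exp2 and nothing else), together with the marginal totals per
#' phenotype.  With `by = "parametrization"` records are first collapsed
#' per parametrization (a parametrization carries a phenotype if any of
#' its per-condition records does), the view matching intersection bars
#' computed across a parametrization's five condition runs.
#'
#' @param membership A membership tibble from [assign_phenotypes()].
#' @param by `"record"` (default) or `"parametrization"`.
#' @return A `cardinality_analysis` object: list with `combinations`
#'   (tibble `combination`, `phenotypes`, `count`), `marginals` (tibble
#'   `phenotype_id`, `count`), `n_units`, `n_assigned` and `by`.
#' @export
cardinality_analysis <- function(membership, by = c("record", "parametrization")) {
  by <- arg_match(by)
  ph_cols <- setdiff(names(membership),
                     c("record_id", "parametrization_id", "condition_id"))
  m <- membership
  if (by == "parametrization") {
    if (!"parametrization_id" %in% names(membership)) {
      abort("`by = \"parametrization\"` needs a parametrization_id column.",
            class = "kin_validation_error")
    }
    m <- membership %>%
      group_by(.data$parametrization_id) %>%
      summarise(across(all_of(ph_cols), any), .groups = "drop")
  }
  sets <- apply(as.matrix(m[, ph_cols, drop = FALSE]), 1,
                function(z) combo_label(ph_cols[z]))
  nonempty <- sets[nzchar(sets)]
  counts <- table(nonempty)
  combos <- tibble(
    combination = names(counts),
    count = as.integer(counts)
  ) %>%
    mutate(phenotypes = map(.data$combination, function(lbl) {
      paste0("exp", strsplit(lbl, "")[[1]])
    })) %>%
    select("combination", "phenotypes", "count") %>%
    arrange(.data$combination)
  marginals <- tibble(
    phenotype_id = ph_cols,
    count = unname(vapply(ph_cols, function(p) sum(m[[p]]), integer(1)))
  )
  structure(list(combinations = combos, marginals = marginals,
                 n_units = nrow(m), n_assigned = length(nonempty), by = by),
            class = "cardinality_analysis")
}

#' @export
print.cardinality_analysis <- function(x, ...) {
  cat("<cardinality_analysis> by ", x$by, ": ", x$n_assigned, " of ",
      x$n_units, " units assigned to >=1 phenotype\n", sep = "")
  print(x$combinations)
  invisible(x)
}

#' @export
tidy.cardinality_analysis <- function(x, ...) {
  x$combinations
}

#' @export
glance.cardinality_analysis <- function(x, ...) {
  tibble(by = x$by, n_units = x$n_units, n_assigned = x$n_assigned,
         n_combinations = nrow(x$combinations))
}
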