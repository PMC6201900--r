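#' Uptake bounds defining an experimental condition
#'
#' The five growth conditions of the E. coli case study each open exactly
#' one carbon source (upper bound 10, conventionally
#' mmol gDW^-1 h^-1) and fix the oxygenation state: exp1 aerobic growth
#' on glucose, exp2 anaerobic growth on glucose (oxygen uptake bounded at
#' 0), exp3 aerobic growth on acetate, exp4 aerobic growth on succinate,
#' exp5 aerobic growth on glycerol.  `exp0` is a rich medium with every
#' carbon source open (not used as a phenotype).  All other carbon
#' uptakes are closed at 0.
#'
#' @param condition_id One of `"exp0"` to `"exp5"`.
#' @param carbon_uptakes Named character vector mapping condition ids to
#'   their carbon-uptake reaction id.
#' @param oxygen Reaction id of the oxygen uptake.
#' @param uptake_bound Upper bound opened for the supplied nutrient.
#' @return A `condition_bounds` tibble with columns `reaction_id`, `lb`,
#'   `ub` and attribute `condition_id`.  Reactions not listed keep their
#'   model bounds.
#' @export
condition_bounds <- function(condition_id,
                             carbon_uptakes = c(exp1 = "GlcUp", exp2 = "GlcUp",
                                                exp3 = "AcUp", exp4 = "SuccUp",
                                                exp5 = "GlycUp"),
                             oxygen = "O2Up",
                             uptake_bound = 10) {
  known <- c("exp0", names(carbon_uptakes))
  if (!condition_id %in% known) {
    abort(paste0("Unknown condition id '", condition_id, "'. Known: ",
                 paste(unique(known), collapse = ", ")),
          class = "kin_config_error")
  }
  all_carbon <- unique(unname(carbon_uptakes))
  if (condition_id == "exp0") {
    open <- all_carbon
  } else {
    open <- carbon_uptakes[[condition_id]]
  }
  closed <- setdiff(all_carbon, open)
  rows <- bind_rows(
    tibble(reaction_id = open, lb = 0, ub = uptake_bound),
    if (length(closed)) tibble(reaction_id = closed, lb = 0, ub = 0),
    tibble(reaction_id = oxygen, lb = 0,
           ub = if (identical(condition_id, "exp2")) 0 else Inf)
  )
  structure(rows, condition_id = condition_id,
            class = c("condition_bounds", class(rows)))
}

#' Flux balance analysis on an irreversible model
#'
#' Solves the linear program max `c v` subject to `S_internal v = 0` and
#' `0 <= v <= ub` with the simplex method.  Internal species are the
#' model species flagged `internal`; external/boundary species are not
#' mass balanced.  Upper bounds default to `Inf` and are overridden by a
#' `condition_bounds` table.  Non-optimal outcomes are reported through
#' the `status` field rather than as errors.
#'
#' @param model An irreversible `metabolic_model` (lower bounds are all 0
#'   by construction).
#' @param bounds Optional [condition_bounds()] tibble (or any data frame
#'   with `reaction_id` and `ub`).
#' @param objective Reaction id to maximize, or a named numeric vector of
#'   objective coefficients.
#' @return An `fba_result`: list with `objective_value`, `fluxes` (tibble
#'   `reaction_id`, `flux`), `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`) and `condition_id`.
#' @export
run_fba <- function(model, bounds = NULL, objective) {
  if (any(model$reactions$reversible)) {
    abort("FBA expects the split irreversible model.",
          class = "kin_validation_error")
  }
  rx_ids <- model$reactions$id
  nr <- length(rx_ids)
  obj <- numeric(nr)
  names(obj) <- rx_ids
  if (is.character(objective)) {
    if (!objective %in% rx_ids) {
      abort(paste0("Objective reaction '", objective, "' not in model."),
            class = "kin_validation_error")
    }
    obj[objective] <- 1
  } else {
    unknown <- setdiff(names(objective), rx_ids)
    if (length(unknown)) {
      abort(paste0("Objective references unknown reactions: ",
                   paste(unknown, collapse = ", ")),
            class = "kin_validation_error")
    }
    obj[names(objective)] <- objective
  }
  ub <- rep(Inf, nr)
  names(ub) <- rx_ids
  if (!is.null(bounds)) {
    unknown <- setdiff(bounds$reaction_id, rx_ids)
    if (length(unknown)) {
      abort(paste0("Bounds reference unknown reactions: ",
                   paste(unknown, collapse = ", ")),
            class = "kin_validation_error")
    }
    ub[bounds$reaction_id] <- bounds$ub
  }
  S <- build_matrices(model)$S
  S_int <- S[model$species$internal, , drop = FALSE]
  res <- lp_solve(unname(obj), unname(S_int), rep(0, nrow(S_int)),
                  unname(ub), maximize = TRUE)
  status <- res$status
  flux <- if (identical(status, "optimal")) res$x else rep(NA_real_, nr)
  structure(list(
    objective_value = if (identical(status, "optimal")) res$value else NA_real_,
    fluxes = tibble(reaction_id = rx_ids, flux = flux),
    status = status,
    objective = obj,
    condition_id = if (!is.null(bounds)) attr(bounds, "condition_id") else NA_character_
  ), class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat("<fba_result> status = ", x$status,
      if (identical(x$status, "optimal"))
        paste0(", objective = ", format(x$objective_value)),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.fba_result <- function(x, ...) {
  x$fluxes
}

#' @export
glance.fba_result <- function(x, ...) {
  tibble(status = x$status, objective_value = x$objective_value,
         condition_id = x$condition_id)
}

#' Condition-discriminating fluxes from per-condition FBA solutions
#'
#' Given one optimal FBA flux vector per condition, classifies reactions
#' into class A (non-zero flux, after the zero-flux threshold, in exactly
#' one condition: the phenotype-marker candidates) and class B (the
#' configured condition-defining reactions: nutrient uptakes and the
#' oxygenation state).  This programmatically reconstructs the filter
#' source table.
#'
#' @param fba_results Named list of `fba_result` objects (names are
#'   condition ids), all with status `"optimal"`.
#' @param condition_defining Character vector of class-B reaction ids.
#' @param epsilon Zero-flux threshold applied before classification.
#' @return A tibble with columns `reaction_id`, `class` (`"A"` or
#'   `"B"`), `condition` (for class A, the single active condition) and
#'   one flux column per condition.
#' @export
derive_filter_targets <- function(fba_results,
                                  condition_defining = c("GlcUp", "AcUp",
                                                         "SuccUp", "GlycUp",
                                                         "GLCptspp",
                                                         "SUCCt2_2pp", "O2Up"),
                                  epsilon = 1e-10) {
  bad <- names(fba_results)[map_chr(fba_results, "status") != "optimal"]
  if (length(bad)) {
    abort(paste0("Non-optimal FBA result for condition(s): ",
                 paste(bad, collapse = ", ")),
          class = "kin_validation_error")
  }
  conds <- names(fba_results)
  flux_tbl <- purrr::reduce(
    imap(fba_results, function(r, cid) {
      stats::setNames(r$fluxes, c("reaction_id", cid))
    }),
    function(a, b) left_join(a, b, by = "reaction_id")
  )
  mat <- threshold_fluxes(as.matrix(flux_tbl[, conds, drop = FALSE]),
                          epsilon = epsilon)
  active <- mat > 0
  n_active <- rowSums(active)
  class_a <- n_active == 1L & !(flux_tbl$reaction_id %in% condition_defining)
  out <- flux_tbl
  out$class <- case_when(
    out$reaction_id %in% condition_defining ~ "B",
    class_a ~ "A",
    TRUE ~ NA_character_
  )
  out$condition <- ifelse(class_a, conds[apply(active, 1, function(z)
    if (sum(z) == 1L) which(z) else NA_integer_)], NA_character_)
  out <- out[!is.na(out$class), c("reaction_id", "class", "condition", conds)]
  as_tibble(out)
}
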