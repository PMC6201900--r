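#' Compute steady-state reaction fluxes from concentrations
#'
#' Evaluates the mass-action law \eqn{v_i = k_i \prod_w x_w^{A_{wi}}} at a
#' single concentration state, normally the final state of a run that
#' passed the steady-state criterion.
#'
#' @param model An irreversible `metabolic_model`.
#' @param k Rate-constant vector.
#' @param concentrations Named numeric vector of concentrations (must
#'   cover every model species).
#' @param parametrization_id,condition_id Provenance labels.
#' @return A `kin_fluxes` tibble with columns `reaction_id` and `flux`
#'   (attribute `thresholded = FALSE`).
#' @export
compute_fluxes <- function(model, k, concentrations,
                           parametrization_id = NA_integer_,
                           condition_id = NA_character_) {
  missing <- setdiff(model$species$id, names(concentrations))
  if (length(missing)) {
    abort(paste0("Concentration vector lacks species: ",
                 paste(missing, collapse = ", ")),
          class = "kin_validation_error")
  }
  rate <- build_rate_law(model, k)
  x <- as.numeric(concentrations[model$species$id])
  v <- rate(x)
  out <- tibble(reaction_id = model$reactions$id, flux = v)
  attr(out, "thresholded") <- FALSE
  attr(out, "parametrization_id") <- parametrization_id
  attr(out, "condition_id") <- condition_id
  class(out) <- c("kin_fluxes", class(out))
  out
}

#' Zero out numerically negligible fluxes
#'
#' Fluxes strictly below `epsilon` are set to exactly zero; a flux equal
#' to `epsilon` is kept.  This tames numerical instability so that the
#' phenotype predicates `> 0` and `= 0` are meaningful.  Thresholding is
#' idempotent.
#'
#' @param fluxes A `kin_fluxes` tibble, a plain numeric vector, or a data
#'   frame of flux records (every numeric column except recognised id
#'   columns is thresholded).
#' @param epsilon Zero-flux threshold, strictly positive (default 1e-10).
#' @return Object of the same shape with small fluxes replaced by 0.
#' @export
threshold_fluxes <- function(fluxes, epsilon = 1e-10) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    abort("`epsilon` must be a single positive number.",
          class = "kin_config_error")
  }
  thr <- function(v) ifelse(v < epsilon, 0, v)
  if (is.numeric(fluxes)) return(thr(fluxes))
  if (!is.data.frame(fluxes)) {
    abort("`fluxes` must be numeric or a data frame.",
          class = "kin_validation_error")
  }
  if ("flux" %in% names(fluxes)) {
    fluxes$flux <- thr(fluxes$flux)
  } else {
    id_cols <- c("parametrization_id", "condition_id", "record_id", "seed",
                 "statistic", "passed", "solver_ok")
    num <- setdiff(names(fluxes)[vapply(fluxes, is.numeric, logical(1))], id_cols)
    for (col in num) fluxes[[col]] <- thr(fluxes[[col]])
  }
  attr(fluxes, "thresholded") <- TRUE
  fluxes
}

#' Write a wide flux table to TSV
#'
#' @param fluxes A data frame of flux records (rows parametrizations,
#'   columns reaction ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flux_table <- function(fluxes, path) {
  readr::write_tsv(as_tibble(fluxes), path)
  invisible(path)
}
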