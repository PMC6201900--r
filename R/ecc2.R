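#' Helpers for the compressed E. coli core model
#'
#' The E. coli case study runs on the compressed core model ECC2comp
#' (distributed as the SBML file `ECC2C.xml` alongside its initial
#' concentration workbook), which is third-party supplementary material
#' and is not bundled with this package.  `ecc2_model_path()` locates a
#' user-supplied copy: first the option `kinensemble.ecc2_model`, then
#' `inst/extdata/ECC2C.xml` of the installed package.  After
#' [split_reversible()] the model has 114 irreversible reactions and 93
#' metabolites (60 internal, 33 external).
#'
#' @return `ecc2_model_path()`: the path, or `NA_character_` if no copy
#'   is available.
#' @export
ecc2_model_path <- function() {
  opt <- getOption("kinensemble.ecc2_model", NULL)
  if (!is.null(opt) && file.exists(opt)) return(opt)
  p <- system.file("extdata", "ECC2C.xml", package = "kinensemble")
  if (nzchar(p) && file.exists(p)) p else NA_character_
}

#' @rdname ecc2_model_path
#' @details `ecc2_concentration_path()` locates a TSV export (columns
#'   `species_id`, `concentration`) of the initial-concentration table,
#'   via the option `kinensemble.ecc2_concentrations` or
#'   `inst/extdata/ECC2_concentrations.tsv`.
#' @export
ecc2_concentration_path <- function() {
  opt <- getOption("kinensemble.ecc2_concentrations", NULL)
  if (!is.null(opt) && file.exists(opt)) return(opt)
  p <- system.file("extdata", "ECC2_concentrations.tsv", package = "kinensemble")
  if (nzchar(p) && file.exists(p)) p else NA_character_
}

#' @rdname ecc2_model_path
#' @details `ecc2_clamped_species()` returns the ions and exchanged
#'   species held at constant concentration throughout the E. coli
#'   simulations.
#' @export
ecc2_clamped_species <- function() {
  c("ac_ex", "ca2_ex", "cl_ex", "co2_ex", "cobalt2_ex", "cu2_ex",
    "fe2_ex", "fe3_ex", "for_ex", "glc_DASH_D_c", "glc_DASH_D_ex",
    "glc_DASH_D_p", "h_ex", "h2_ex", "h2o_ex", "k_ex", "mg2_ex",
    "mn2_ex", "mobd_ex", "MTHTHF_ex", "nh4_ex", "ni2_ex", "o2_ex",
    "pi_ex", "so4_ex", "succ_ex", "zn2_ex")
}

#' @rdname ecc2_model_path
#' @details `ecc2_reference_growth_rates()` returns the published
#'   FBA-maximal growth rates per condition, used as the reference when a
#'   model copy is available.
#' @export
ecc2_reference_growth_rates <- function() {
  c(exp1 = 0.982, exp2 = 0.289, exp3 = 0.244, exp4 = 0.492, exp5 = 0.563)
}
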