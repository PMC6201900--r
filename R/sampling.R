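#' Configuration of a kinetic-constant ensemble
#'
#' @param P Number of parametrizations to draw (>= 1).
#' @param low,high Uniform sampling bounds for every rate constant;
#'   defaults to the `[0, 100)` interval.
#' @param master_seed Integer seed from which per-parametrization
#'   sub-seeds are derived.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(P, low = 0, high = 100, master_seed = 1L) {
  if (!is.numeric(P) || length(P) != 1L || P < 1) {
    abort("`P` must be a single integer >= 1.", class = "kin_config_error")
  }
  if (!is.numeric(low) || !is.numeric(high) || low < 0 || low >= high) {
    abort("Sampling bounds need 0 <= low < high.", class = "kin_config_error")
  }
  structure(list(P = as.integer(P), low = low, high = high,
                 master_seed = as.integer(master_seed)),
            class = "ensemble_config")
}

# Counter-based sub-seed: two rounds of a Lehmer-style mix of the master
# seed and the parametrization index, kept below 2^31 - 1.  Exact in
# double arithmetic (all intermediates < 2^53).
sub_seed <- function(master_seed, p) {
  m <- 2147483647
  s <- (as.numeric(master_seed) %% m)
  s <- (s * 48271 + as.numeric(p)) %% m
  s <- (s * 48271 + as.numeric(p)) %% m
  as.integer(s)
}

with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Sample random kinetic-constant parametrizations
#'
#' Draws `P` vectors of rate constants, one constant per (already split,
#' hence directional) reaction, i.i.d. uniform on `[low, high)`.  Each
#' parametrization uses its own sub-seed derived deterministically from
#' the master seed, so the set is reproducible and individual vectors can
#' be regenerated in isolation.
#'
#' @param model An irreversible `metabolic_model`.
#' @param config An [ensemble_config()].
#' @return A tibble with columns `parametrization_id`, `seed` and one
#'   numeric column per reaction (in model order).
#' @examples
#' m <- make_linear_chain(2, x0 = 1, k = c(1, 1, 1))$model
#' sample_parametrizations(m, ensemble_config(P = 3, master_seed = 42))
#' @export
sample_parametrizations <- function(model, config) {
  if (!inherits(config, "ensemble_config")) {
    abort("`config` must be an ensemble_config().", class = "kin_config_error")
  }
  if (any(model$reactions$reversible)) {
    abort("Sample on the split (irreversible) model.", class = "kin_validation_error")
  }
  M <- n_reactions(model)
  seeds <- vapply(seq_len(config$P), function(p) sub_seed(config$master_seed, p),
                  integer(1))
  draws <- with_preserved_rng({
    map(seeds, function(s) {
      set.seed(s)
      runif(M, config$low, config$high)
    })
  })
  mat <- do.call(rbind, draws)
  colnames(mat) <- model$reactions$id
  dplyr::bind_cols(
    tibble(parametrization_id = seq_len(config$P), seed = seeds),
    as_tibble(mat)
  )
}

#' Extract the rate-constant matrix from a parametrization table
#'
#' @param params A tibble from [sample_parametrizations()].
#' @param model The model the parametrizations belong to.
#' @return A numeric matrix (parametrizations by reactions), rows named by
#'   `parametrization_id`.
#' @export
param_matrix <- function(params, model) {
  ids <- model$reactions$id
  missing <- setdiff(ids, names(params))
  if (length(missing)) {
    abort(paste0("Parametrization table lacks reactions: ",
                 paste(missing, collapse = ", ")),
          class = "kin_validation_error")
  }
  mat <- as.matrix(params[, ids, drop = FALSE])
  rownames(mat) <- params$parametrization_id
  mat
}
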