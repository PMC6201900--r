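#' Build the mass-action rate law of a model
#'
#' Returns a function mapping a concentration vector (model species order)
#' to the vector of instantaneous reaction rates
#' \eqn{v_i = k_i \prod_w x_w^{A_{wi}}}, where `A` holds the reactant-side
#' stoichiometric coefficients.  A reaction with an empty reactant side
#' has rate `k` (empty product convention).  Concentrations are clipped at
#' zero before evaluation.  Reactions with more than `log_space_above`
#' reactant species (e.g. a biomass pseudo-reaction) are evaluated in log
#' space to avoid premature under/overflow.
#'
#' @param model An irreversible `metabolic_model`.
#' @param k Numeric vector of non-negative rate constants, one per
#'   reaction.
#' @param log_space_above Reactant-count threshold for log-space
#'   evaluation.
#' @return A function `f(x) -> v` with attribute `"matrices"` holding the
#'   `S`/`A` pair used.
#' @export
build_rate_law <- function(model, k, log_space_above = 10L) {
  if (length(k) != n_reactions(model)) {
    abort("`k` must have one rate constant per reaction.",
          class = "kin_validation_error")
  }
  if (any(k < 0)) {
    abort("Rate constants must be non-negative.", class = "kin_validation_error")
  }
  mats <- build_matrices(model)
  A <- mats$A
  idx <- map(seq_len(ncol(A)), ~ which(A[, .x] > 0))
  ords <- map2(idx, seq_along(idx), ~ A[.x, .y])
  k <- as.numeric(k)
  f <- function(x) {
    x <- pmax(x, 0)
    v <- k
    for (i in seq_along(v)) {
      w <- idx[[i]]
      if (length(w) == 0L) next
      if (length(w) > log_space_above) {
        xi <- x[w]
        if (any(xi == 0)) {
          v[i] <- 0
        } else {
          v[i] <- k[i] * exp(sum(ords[[i]] * log(xi)))
        }
      } else {
        v[i] <- k[i] * prod(x[w]^ords[[i]])
      }
    }
    v
  }
  attr(f, "matrices") <- mats
  f
}

#' Integrate the mass-action ODE system
#'
#' Integrates \eqn{\dot x = S v(x)} with LSODA (stiff/non-stiff switching)
#' on a fixed output grid over `[0, t_end]`.  Clamped species have their
#' derivative forced to zero and their trajectory row is bit-exactly equal
#' to the initial value.  Output concentrations are clipped at zero.
#' Solver failures raise a condition of class `kin_integration_error`
#' carrying the parametrization id, so callers can count discarded
#' samplings instead of losing them silently.
#'
#' @param model An irreversible `metabolic_model` with initial
#'   concentrations set.
#' @param k Rate-constant vector (one per reaction).
#' @param t_end Simulation horizon in seconds (default 100, long enough
#'   for central metabolism to relax after a nutrient pulse).
#' @param n_points Number of output grid points (default 1001, so the
#'   final 10 percent window holds 101 points).
#' @param rtol,atol Relative / absolute solver tolerances.
#' @param parametrization_id,condition_id Provenance labels carried in the
#'   trajectory.
#' @return A `kin_trajectory`: list with `times`, `concentrations`
#'   (timepoints by species matrix), `species` (the model species table)
#'   and provenance fields.
#' @export
simulate_dynamics <- function(model, k, t_end = 100, n_points = 1001,
                              rtol = 1e-6, atol = 1e-9,
                              parametrization_id = NA_integer_,
                              condition_id = NA_character_) {
  if (t_end <= 0) abort("`t_end` must be positive.", class = "kin_config_error")
  rate <- build_rate_law(model, k)
  S <- attr(rate, "matrices")$S
  y0 <- stats::setNames(model$species$initial_concentration, model$species$id)
  clamped_idx <- which(model$species$clamped)
  times <- seq(0, t_end, length.out = n_points)
  rhs <- function(t, y, parms) {
    dy <- as.vector(S %*% rate(y))
    if (length(clamped_idx)) dy[clamped_idx] <- 0
    list(dy)
  }
  fail <- function(msg) {
    abort(paste0("ODE integration failed",
                 if (!is.na(parametrization_id))
                   paste0(" (parametrization ", parametrization_id, ")"),
                 ": ", msg),
          class = "kin_integration_error",
          parametrization_id = parametrization_id,
          condition_id = condition_id)
  }
  out <- withCallingHandlers(
    tryCatch(
      deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol, atol = atol),
      error = function(e) fail(conditionMessage(e))
    ),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (nrow(out) < length(times) || anyNA(out[, -1])) {
    fail("solver did not reach the end of the integration horizon")
  }
  conc <- unname(as.matrix(out[, -1, drop = FALSE]))
  colnames(conc) <- model$species$id
  conc[conc < 0] <- 0
  if (length(clamped_idx)) {
    for (j in clamped_idx) conc[, j] <- y0[[j]]
  }
  structure(list(times = times,
                 concentrations = conc,
                 species = model$species,
                 parametrization_id = parametrization_id,
                 condition_id = condition_id),
            class = "kin_trajectory")
}

#' @export
print.kin_trajectory <- function(x, ...) {
  cat("<kin_trajectory> ", length(x$times), " timepoints x ",
      ncol(x$concentrations), " species over [0, ",
      format(max(x$times)), "]\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.kin_trajectory <- function(x, ...) {
  tibble(
    time = rep(x$times, times = ncol(x$concentrations)),
    species_id = rep(colnames(x$concentrations), each = length(x$times)),
    concentration = as.vector(x$concentrations)
  )
}

#' Final concentration state of a trajectory
#' @param trajectory A `kin_trajectory`.
#' @return Named numeric vector of concentrations at the last timepoint.
#' @export
final_state <- function(trajectory) {
  stats::setNames(trajectory$concentrations[nrow(trajectory$concentrations), ],
                  colnames(trajectory$concentrations))
}

#' Quantified steady-state criterion
#'
#' A simulation counts as steady at its ending time when the mean
#' per-species standard deviation of the concentrations over the final
#' window falls below a tolerance `theta`:
#' \deqn{\frac{\sum_w \sigma([x_w](\bar t, t_e))}{M - S} < \theta,}
#' with \eqn{\bar t = 0.9\, t_e} by default, `M` the number of species
#' entering the sum and `S` the number of excluded species (clamped
#' species plus species flagged not internal, e.g. accumulating products
#' such as biomass).  Excluded species contribute exactly zero to the
#' numerator.  The optional relative mode divides each sigma by the window
#' mean (skipping near-zero means), useful when concentrations span
#' scales.
#'
#' @param trajectory A `kin_trajectory`.
#' @param theta Tolerance threshold (default 0.001, i.e. 0.1 percent).
#' @param window_fraction Fraction of the horizon forming the evaluation
#'   window (default 0.1, the final 10 percent).
#' @param relative If `TRUE`, use sigma divided by the window mean.
#' @return A `steady_state_report` with `statistic`, `theta`,
#'   `window_start`, `passed` and a per-species sigma table.
#' @export
check_steady_state <- function(trajectory, theta = 0.001,
                               window_fraction = 0.1, relative = FALSE) {
  t_e <- max(trajectory$times)
  window_start <- (1 - window_fraction) * t_e
  in_window <- trajectory$times >= window_start - 1e-12 * t_e
  if (sum(in_window) < 3L) {
    abort("Steady-state window holds fewer than 3 grid points.",
          class = "kin_criterion_error")
  }
  sp <- trajectory$species
  excluded <- sp$clamped | !sp$internal
  win <- trajectory$concentrations[in_window, , drop = FALSE]
  sigma <- apply(win, 2, stats::sd)
  if (relative) {
    mu <- colMeans(win)
    sigma <- ifelse(mu > 1e-12, sigma / mu, 0)
  }
  sigma[excluded] <- 0
  M <- nrow(sp)
  S <- sum(excluded)
  if (M == S) {
    abort("All species are excluded from the steady-state criterion.",
          class = "kin_criterion_error")
  }
  statistic <- sum(sigma) / (M - S)
  structure(list(
    statistic = statistic,
    theta = theta,
    window_start = window_start,
    passed = statistic < theta,
    per_species_sigma = tibble(species_id = sp$id, sigma = unname(sigma),
                               excluded = excluded),
    relative = relative,
    parametrization_id = trajectory$parametrization_id,
    condition_id = trajectory$condition_id
  ), class = "steady_state_report")
}

#' @export
print.steady_state_report <- function(x, ...) {
  cat("<steady_state_report> statistic = ", format(x$statistic),
      " (theta = ", format(x$theta), ") -> ",
      if (x$passed) "steady" else "NOT steady", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.steady_state_report <- function(x, ...) {
  x$per_species_sigma
}

#' @export
glance.steady_state_report <- function(x, ...) {
  tibble(statistic = x$statistic, theta = x$theta,
         window_start = x$window_start, passed = x$passed,
         relative = x$relative)
}

#' Net production residual at the end of a trajectory
#'
#' Maximum absolute net production rate `|S v(x(t_e))|` over internal,
#' unclamped species.  For a trajectory certified steady by
#' [check_steady_state()] this residual is small and shrinks as `theta`
#' is tightened.
#'
#' @param model The simulated `metabolic_model`.
#' @param k Rate constants used for the run.
#' @param trajectory The resulting `kin_trajectory`.
#' @return A non-negative scalar.
#' @export
steady_state_residual <- function(model, k, trajectory) {
  rate <- build_rate_law(model, k)
  S <- attr(rate, "matrices")$S
  x <- final_state(trajectory)
  dx <- as.vector(S %*% rate(x))
  keep <- model$species$internal & !model$species$clamped
  if (!any(keep)) return(0)
  max(abs(dx[keep]))
}
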