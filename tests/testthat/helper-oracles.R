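# Independent brute-force oracles, deliberately naive so they share no
# code path with the implementation they check.

# Two-sample KS statistic as the maximum empirical-CDF gap over the
# pooled sample points.
oracle_ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(p) mean(x <= p), numeric(1))
  fy <- vapply(pts, function(p) mean(y <= p), numeric(1))
  max(abs(fx - fy))
}

# Predicate-by-predicate filter evaluation for one wide flux record.
oracle_assign <- function(flux_row, filters) {
  phenos <- unique(filters$phenotype_id)
  out <- character(0)
  for (ph in phenos) {
    preds <- filters[filters$phenotype_id == ph, ]
    ok <- TRUE
    for (j in seq_len(nrow(preds))) {
      v <- flux_row[[preds$reaction_id[j]]]
      ok <- ok && if (preds$comparator[j] == "greater_than_zero") v > 0 else v == 0
    }
    if (ok) out <- c(out, ph)
  }
  out
}

# Sort-based median, no stats::median.
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Exhaustive vertex enumeration for max c'v, S v = 0, 0 <= v <= ub with
# every ub finite.  Tries all free/at-zero/at-ub assignments and solves
# the equality system for the free variables.
oracle_lp_max <- function(S, ub, obj, tol = 1e-8) {
  n <- ncol(S)
  best <- -Inf
  states <- expand.grid(rep(list(0:2), n))  # 0 free, 1 at 0, 2 at ub
  for (row in seq_len(nrow(states))) {
    st <- as.integer(states[row, ])
    free <- which(st == 0L)
    v <- ifelse(st == 2L, ub, 0)
    rhs <- -as.vector(S %*% v)
    if (length(free)) {
      sol <- tryCatch(qr.solve(S[, free, drop = FALSE], rhs, tol = 1e-10),
                      error = function(e) NULL)
      if (is.null(sol)) next
      v[free] <- sol
    }
    if (max(abs(S %*% v)) > tol) next
    if (any(v < -tol) || any(v > ub + tol)) next
    val <- sum(obj * v)
    if (val > best) best <- val
  }
  best
}

# Uniform random irreversible toy network with finite uptake bounds,
# guaranteed feasible (zero flux always is).
random_toy_network <- function(seed, n_species = 3, n_reactions = 5) {
  set.seed(seed)
  sp <- c("ext_in", paste0("M", seq_len(n_species)), "ext_out")
  internal <- c(FALSE, rep(TRUE, n_species), FALSE)
  make_rx <- function(i) {
    from <- sample(sp[-length(sp)], 1)
    to <- sample(setdiff(sp[-1], from), 1)
    tibble::tibble(id = paste0("R", i), reversible = FALSE,
                   reactants = list(stats::setNames(1, from)),
                   products = list(stats::setNames(1, to)))
  }
  rx <- dplyr::bind_rows(lapply(seq_len(n_reactions), make_rx))
  metabolic_model(
    species = tibble::tibble(id = sp, internal = internal,
                             clamped = !internal,
                             initial_concentration = 1),
    reactions = rx
  )
}
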