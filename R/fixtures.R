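#' Linear chain model with a closed-form steady state
#'
#' Builds the mass-action chain
#' `X0 (clamped) -> X1 -> ... -> Xn -> (sink)` with rate constants
#' `k = (k1, ..., k_{n+1})`.  With a clamped source at concentration
#' `x0`, the analytic steady state is a uniform throughput `J = k1 * x0`
#' with `[Xi] = J / k_{i+1}`.  If any downstream constant is zero the
#' chain has no finite steady state (the species upstream of the dead
#' step accumulates linearly), which is the canonical fixture for a run
#' that must fail the steady-state criterion.
#'
#' @param n Chain length (number of internal species), >= 1.
#' @param x0 Clamped source concentration.
#' @param k Rate constants, length `n + 1`, non-negative.
#' @return A list with `model` (a `metabolic_model`; internal species
#'   start at 0), `steady_state` (named vector, or `NULL` when no finite
#'   steady state exists), `fluxes` (named vector of the uniform
#'   throughput per reaction, or `NULL`) and `throughput`.
#' @examples
#' ch <- make_linear_chain(1, x0 = 1, k = c(2, 4))
#' ch$steady_state  # X1 = 0.5
#' ch$throughput    # J = 2
#' @export
make_linear_chain <- function(n, x0 = 1, k = rep(1, n + 1)) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("Chain length `n` must be >= 1.", class = "kin_config_error")
  }
  n <- as.integer(n)
  if (length(k) != n + 1L) {
    abort("`k` must have length n + 1.", class = "kin_config_error")
  }
  if (any(k < 0)) abort("Rate constants must be non-negative.",
                        class = "kin_config_error")
  ids <- c("X0", paste0("X", seq_len(n)))
  species <- tibble(
    id = ids,
    internal = c(FALSE, rep(TRUE, n)),
    clamped = c(TRUE, rep(FALSE, n)),
    initial_concentration = c(x0, rep(0, n))
  )
  reactions <- tibble(
    id = paste0("R", seq_len(n + 1L)),
    reversible = FALSE,
    reactants = map(seq_len(n + 1L), function(i) {
      stats::setNames(1, ids[i])
    }),
    products = map(seq_len(n + 1L), function(i) {
      if (i <= n) stats::setNames(1, ids[i + 1L])
      else stats::setNames(numeric(0), character(0))
    })
  )
  model <- metabolic_model(species, reactions)
  finite <- all(k[-1] > 0) && k[1] >= 0
  J <- k[1] * x0
  steady <- if (finite) stats::setNames(J / k[-1], ids[-1]) else NULL
  fluxes <- if (finite) stats::setNames(rep(J, n + 1L), reactions$id) else NULL
  list(model = model, steady_state = steady, fluxes = fluxes,
       throughput = if (finite) J else NA_real_, k = k)
}

valid_phenotype_subset <- function(subset) {
  !("exp2" %in% subset && length(setdiff(subset, "exp2")) > 0)
}

#' Synthetic flux records with planted phenotype memberships
#'
#' Generates flux vectors over the sixteen marker reactions of the
#' built-in filters, with known (planted) phenotype membership for each
#' record, including empty and multi-phenotype cases.  Membership subsets
#' containing the anaerobic phenotype (exp2, which requires zero oxygen
#' uptake) together with any aerobic phenotype are structurally
#' impossible and are refused.
#'
#' @param seed Fixture seed (its own namespace, independent of the
#'   sampling module).
#' @param n_records Number of records to generate.
#' @param planted Optional list of character vectors: the membership
#'   subset of each record.  When `NULL`, subsets are drawn at random
#'   from the valid ones (including the empty set and the all-aerobic
#'   quadruple).
#' @return A list with `fluxes` (tibble `record_id` + marker columns,
#'   already consistent with a 1e-10 threshold) and `truth` (tibble
#'   `record_id` + one logical column per phenotype).
#' @export
make_phenotype_fixture <- function(seed, n_records = 100, planted = NULL) {
  filters <- builtin_filters()
  phenos <- unique(filters$phenotype_id)
  markers <- unique(filters$reaction_id)
  if (!is.null(planted)) {
    bad <- which(!map_lgl(planted, valid_phenotype_subset))
    if (length(bad)) {
      abort(paste0("Planted subset ", bad[1],
                   " combines the anaerobic phenotype with an aerobic one; ",
                   "no flux vector can satisfy both oxygen predicates."),
            class = "kin_config_error")
    }
    n_records <- length(planted)
  }
  with_preserved_rng({
    set.seed(sub_seed(seed, 104729L))
    subsets <- planted %||% map(seq_len(n_records), function(i) {
      repeat {
        s <- phenos[runif(length(phenos)) < 0.35]
        if (valid_phenotype_subset(s)) return(s)
      }
    })
    rows <- map(seq_along(subsets), function(i) {
      s <- subsets[[i]]
      v <- stats::setNames(rep(0, length(markers)), markers)
      if (length(s)) {
        if ("exp2" %in% s) {
          v["O2Up"] <- 0
        } else {
          v["O2Up"] <- runif(1, 0.5, 20)
        }
        for (ph in s) {
          preds <- filters[filters$phenotype_id == ph, ]
          pos <- preds$reaction_id[preds$comparator == "greater_than_zero"]
          for (r in pos) if (v[[r]] == 0) v[[r]] <- runif(1, 0.5, 10)
        }
      }
      as_tibble(as.list(v))
    })
    fluxes <- bind_cols(tibble(record_id = seq_len(n_records)), bind_rows(rows))
    truth <- bind_cols(
      tibble(record_id = seq_len(n_records)),
      as_tibble(stats::setNames(
        map(phenos, function(p) map_lgl(subsets, ~ p %in% .x)), phenos))
    )
    list(fluxes = fluxes, truth = truth, subsets = subsets)
  })
}

#' Synthetic marker network for condition-resolved flux balance analysis
#'
#' A small irreversible network carrying the sixteen marker reactions of
#' the built-in phenotype filters, wired so that maximizing biomass under
#' each growth condition's uptake bounds activates exactly that
#' phenotype's markers: glucose is oxidized through
#' GLCptspp/G6PDH2r/GND/PGL (yield 2) when oxygen is open and fermented
#' through ALCD2x with forced acetate/ethanol export (yield 1) when it is
#' closed; acetate runs through ICL/MALS, succinate through
#' SUCCt2_2pp/ME2 and glycerol through GLYK/GLYCDx/F6PA, each consuming
#' oxygen.  All routes feed a common precursor drained by the `Biomass`
#' reaction.
#'
#' @return A `metabolic_model` with 23 species and 20 reactions.
#' @export
make_marker_network <- function() {
  ext <- c("glc_e", "ac_e", "succ_e", "glyc_e", "o2_e",
           "etoh_x", "ac_x", "bm_x")
  int <- c("glc_c", "ac_c", "succ_c", "glyc_c", "o2_c", "glc6p", "g1",
           "g2", "glx", "succ_p", "g3p", "dha", "etoh_c", "ac2_c", "X")
  species <- tibble(
    id = c(ext, int),
    internal = c(rep(FALSE, length(ext)), rep(TRUE, length(int))),
    clamped = c(rep(TRUE, length(ext)), rep(FALSE, length(int))),
    initial_concentration = c(rep(1, length(ext)), rep(0, length(int)))
  )
  rx <- function(id, reactants, products) {
    tibble(id = id, reversible = FALSE,
           reactants = list(reactants), products = list(products))
  }
  reactions <- bind_rows(
    rx("GlcUp", c(glc_e = 1), c(glc_c = 1)),
    rx("AcUp", c(ac_e = 1), c(ac_c = 1)),
    rx("SuccUp", c(succ_e = 1), c(succ_c = 1)),
    rx("GlycUp", c(glyc_e = 1), c(glyc_c = 1)),
    rx("O2Up", c(o2_e = 1), c(o2_c = 1)),
    rx("GLCptspp", c(glc_c = 1), c(glc6p = 1)),
    rx("G6PDH2r", c(glc6p = 1, o2_c = 1), c(g1 = 1)),
    rx("GND", c(g1 = 1), c(g2 = 1)),
    rx("PGL", c(g2 = 1), c(X = 2)),
    rx("ALCD2x", c(glc6p = 1), c(etoh_c = 1, ac2_c = 1, X = 1)),
    rx("EthEx", c(etoh_c = 1), c(etoh_x = 1)),
    rx("AcEx", c(ac2_c = 1), c(ac_x = 1)),
    rx("ICL", c(ac_c = 1, o2_c = 1), c(glx = 1)),
    rx("MALS", c(glx = 1), c(X = 1)),
    rx("SUCCt2_2pp", c(succ_c = 1), c(succ_p = 1)),
    rx("ME2", c(succ_p = 1, o2_c = 1), c(X = 1)),
    rx("GLYK", c(glyc_c = 1), c(g3p = 1)),
    rx("GLYCDx", c(g3p = 1, o2_c = 1), c(dha = 1)),
    rx("F6PA", c(dha = 1), c(X = 1)),
    rx("Biomass", c(X = 1), c(bm_x = 1))
  )
  metabolic_model(species, reactions)
}

#' Synthetic per-condition flux samples with a planted relevant set
#'
#' Builds five condition sample sets per reaction: planted *relevant*
#' reactions have all five condition means separated by `effect_size`
#' standard deviations (every pair differs), *partial* reactions shift
#' only one condition (pairs among the remaining four coincide, so they
#' must never be called relevant), and *null* reactions share one
#' distribution across conditions.
#'
#' @param seed Fixture seed.
#' @param effect_size Separation between adjacent condition means, in
#'   units of the (unit) standard deviation.
#' @param n Samples per condition per reaction (>= 10).
#' @param n_relevant,n_partial,n_null Number of reactions of each kind.
#' @return A list with `samples` (long tibble `condition_id`,
#'   `reaction_id`, `value`) and `relevant` (character vector of planted
#'   relevant reaction ids).
#' @export
make_ks_fixture <- function(seed, effect_size, n, n_relevant = 2,
                            n_partial = 1, n_null = 5) {
  if (n < 10) abort("`n` must be >= 10.", class = "kin_config_error")
  conds <- paste0("exp", 1:5)
  with_preserved_rng({
    set.seed(sub_seed(seed, 7919L))
    gen <- function(name, means) {
      bind_rows(map(seq_along(conds), function(i) {
        tibble(condition_id = conds[i], reaction_id = name,
               value = stats::rnorm(n, mean = means[i], sd = 1))
      }))
    }
    samples <- list()
    relevant <- character(0)
    for (j in seq_len(n_relevant)) {
      nm <- paste0("rel_", j)
      samples[[nm]] <- gen(nm, effect_size * (0:4))
      relevant <- c(relevant, nm)
    }
    for (j in seq_len(n_partial)) {
      nm <- paste0("part_", j)
      samples[[nm]] <- gen(nm, c(0, 0, 0, 0, effect_size))
    }
    for (j in seq_len(n_null)) {
      nm <- paste0("null_", j)
      samples[[nm]] <- gen(nm, rep(0, 5))
    }
    list(samples = bind_rows(samples),
         relevant = if (effect_size > 0) sort(relevant) else character(0))
  })
}
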