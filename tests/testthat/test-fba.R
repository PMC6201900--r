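toy_chain_lp <- function() {
  metabolic_model(
    tibble::tibble(id = c("Ext", "A", "Out"), internal = c(FALSE, TRUE, FALSE),
                   clamped = c(TRUE, FALSE, TRUE), initial_concentration = 1),
    tibble::tibble(id = c("Up", "Obj"), reversible = FALSE,
                   reactants = list(c(Ext = 1), c(A = 1)),
                   products = list(c(A = 1), c(Out = 1)))
  )
}

test_that("condition bounds open exactly one carbon source", {
  b1 <- condition_bounds("exp1")
  expect_equal(b1$ub[b1$reaction_id == "GlcUp"], 10)
  expect_equal(b1$ub[b1$reaction_id == "O2Up"], Inf)
  expect_equal(b1$ub[b1$reaction_id == "AcUp"], 0)
  expect_equal(sum(b1$ub > 0 & b1$reaction_id != "O2Up"), 1)

  b2 <- condition_bounds("exp2")
  expect_equal(b2$ub[b2$reaction_id == "O2Up"], 0)
  expect_equal(b2$ub[b2$reaction_id == "GlcUp"], 10)

  b4 <- condition_bounds("exp4")
  expect_equal(b4$ub[b4$reaction_id == "SuccUp"], 10)

  b0 <- condition_bounds("exp0")
  expect_true(all(b0$ub[b0$reaction_id %in%
                          c("GlcUp", "AcUp", "SuccUp", "GlycUp")] == 10))

  expect_error(condition_bounds("exp9"), class = "kin_config_error")
})

test_that("linear programs on toy networks solve to the hand-derived optimum", {
  m <- toy_chain_lp()
  r <- run_fba(m, tibble::tibble(reaction_id = "Up", ub = 10), objective = "Obj")
  expect_equal(r$status, "optimal")
  expect_equal(r$objective_value, 10)
  expect_equal(tidy(r)$flux, c(10, 10))

  # all uptakes closed: only the zero flux is feasible
  r0 <- run_fba(m, tibble::tibble(reaction_id = "Up", ub = 0), objective = "Obj")
  expect_equal(r0$status, "optimal")
  expect_equal(r0$objective_value, 0)

  # no bound at all: the chain is an unbounded ray
  ru <- run_fba(m, objective = "Obj")
  expect_equal(ru$status, "unbounded")
  expect_true(is.na(ru$objective_value))
})

test_that("the simplex optimum equals exhaustive vertex enumeration", {
  for (seed in 1:6) {
    m <- random_toy_network(seed, n_species = 3, n_reactions = 5)
    set.seed(seed + 100)
    ub <- runif(5, 1, 10)
    obj <- m$reactions$id[sample(5, 1)]
    r <- run_fba(m, tibble::tibble(reaction_id = m$reactions$id, ub = ub),
                 objective = obj)
    expect_equal(r$status, "optimal")
    S_int <- build_matrices(m)$S[m$species$internal, , drop = FALSE]
    cvec <- as.numeric(m$reactions$id == obj)
    expect_equal(r$objective_value, oracle_lp_max(S_int, ub, cvec),
                 tolerance = 1e-7)
  }
})

test_that("the FBA optimum is invariant under reaction and species reordering", {
  m <- make_marker_network()
  r <- run_fba(m, condition_bounds("exp1"), objective = "Biomass")
  set.seed(1)
  perm_rx <- sample(n_reactions(m))
  perm_sp <- sample(n_species(m))
  m2 <- metabolic_model(m$species[perm_sp, ], m$reactions[perm_rx, ])
  r2 <- run_fba(m2, condition_bounds("exp1"), objective = "Biomass")
  expect_equal(r2$objective_value, r$objective_value)
})

test_that("every condition's FBA vector satisfies its own phenotype filter", {
  m <- make_marker_network()
  for (cid in paste0("exp", 1:5)) {
    r <- run_fba(m, condition_bounds(cid), objective = "Biomass")
    expect_equal(r$status, "optimal")
    fl <- tidy(r)
    wide <- tibble::as_tibble(as.list(stats::setNames(
      threshold_fluxes(fl$flux), fl$reaction_id)))
    expect_true(cid %in% phenotype_set(wide),
                label = paste0("FBA vector of ", cid, " satisfies its filter"))
  }
})

test_that("condition-discriminating reactions are classified from FBA vectors", {
  m <- make_marker_network()
  res <- lapply(stats::setNames(paste0("exp", 1:5), paste0("exp", 1:5)),
                function(cid) run_fba(m, condition_bounds(cid),
                                      objective = "Biomass"))
  tg <- derive_filter_targets(res)
  # the class-A scan recovers exactly the bold-style single-condition markers
  a <- tg[tg$class == "A", ]
  expected_a <- list(exp1 = c("G6PDH2r", "GND", "PGL"),
                     exp2 = c("ALCD2x", "EthEx", "AcEx"),
                     exp3 = c("ICL", "MALS"),
                     exp4 = "ME2",
                     exp5 = c("GLYK", "GLYCDx", "F6PA"))
  for (cid in names(expected_a)) {
    expect_setequal(a$reaction_id[a$condition == cid], expected_a[[cid]])
  }
  # condition-defining reactions are reported as class B, never class A
  expect_true(all(tg$class[tg$reaction_id %in%
                             c("GlcUp", "AcUp", "SuccUp", "GlycUp",
                               "O2Up", "GLCptspp", "SUCCt2_2pp")] == "B"))
  # a reaction active in two conditions is excluded from class A
  expect_false("GLCptspp" %in% a$reaction_id)

  res$exp1$status <- "infeasible"
  expect_error(derive_filter_targets(res), class = "kin_validation_error")
})

test_that("planted one-condition reactions are recovered from a flux table", {
  conds <- paste0("exp", 1:5)
  mk_res <- function(flux_by_rx) {
    lapply(stats::setNames(seq_along(conds), conds), function(i) {
      structure(list(
        status = "optimal",
        objective_value = 1,
        fluxes = tibble::tibble(reaction_id = names(flux_by_rx),
                                flux = vapply(flux_by_rx, `[[`, numeric(1), i)),
        condition_id = conds[i]), class = "fba_result")
    })
  }
  res <- mk_res(list(only1 = c(4.142, 0, 0, 0, 0),
                     shared = c(1, 2, 0, 0, 0),
                     never = c(0, 0, 0, 0, 0),
                     only5 = c(0, 0, 0, 0, 5.414)))
  tg <- derive_filter_targets(res, condition_defining = character(0))
  expect_setequal(tg$reaction_id[tg$class == "A"], c("only1", "only5"))
  expect_equal(tg$condition[tg$reaction_id == "only1"], "exp1")
  expect_equal(tg$condition[tg$reaction_id == "only5"], "exp5")
})
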