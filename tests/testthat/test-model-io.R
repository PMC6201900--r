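test_that("tabular dialect parses equations into models", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation", "R1\tA + B -> C"), path)
  m <- read_reaction_table(path)
  expect_s3_class(m, "metabolic_model")
  expect_equal(n_species(m), 3)
  expect_equal(n_reactions(m), 1)
  expect_false(m$reactions$reversible)
  expect_equal(m$reactions$reactants[[1]], c(A = 1, B = 1))

  eq <- parse_equation("2 A + B <-> 0.5 C")
  expect_true(eq$reversible)
  expect_equal(eq$reactants, c(A = 2, B = 1))
  expect_equal(eq$products, c(C = 0.5))

  # exchange reactions may have one empty side
  expect_length(parse_equation("A ->")$products, 0)
  expect_length(parse_equation("-> A")$reactants, 0)
})

test_that("duplicate ids are rejected", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation", "R1\tA -> B", "R1\tB -> C"), path)
  expect_error(read_reaction_table(path), class = "kin_validation_error")
  expect_error(
    metabolic_model(tibble::tibble(id = c("A", "A")),
                    tibble::tibble(id = "R1", reversible = FALSE,
                                   reactants = list(c(A = 1)),
                                   products = list(c(A = 1)))),
    class = "kin_validation_error"
  )
})

test_that("reactions referencing unknown species are rejected", {
  expect_error(
    metabolic_model(tibble::tibble(id = "A"),
                    tibble::tibble(id = "R1", reversible = FALSE,
                                   reactants = list(c(A = 1)),
                                   products = list(c(Z = 1)))),
    class = "kin_validation_error"
  )
})

test_that("tabular serialization round-trips on canonical form", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation",
               "R1\t2 A + B -> C",
               "R2\tC <-> D",
               "R3\tD ->"), path)
  m1 <- read_reaction_table(path)
  out <- tempfile(fileext = ".tsv")
  write_reaction_table(m1, out)
  m2 <- read_reaction_table(out)
  expect_equal(m2$reactions, m1$reactions)
})

test_that("split_reversible replaces each reversible reaction by a directional pair", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation", "PGM\tA <-> B"), path)
  m <- split_reversible(read_reaction_table(path))
  expect_equal(m$reactions$id, c("PGM", "PGM_reverse"))
  expect_false(any(m$reactions$reversible))
  expect_equal(m$reactions$reactants[[2]], c(B = 1))
  expect_equal(m$reactions$products[[2]], c(A = 1))

  # a fully irreversible model is a fixed point
  chain <- make_linear_chain(2, 1, c(1, 1, 1))$model
  expect_equal(split_reversible(chain), chain)
})

test_that("split reaction count is irreversible + 2 x reversible on random models", {
  for (seed in 1:5) {
    n_irr <- sample(1:4, 1)
    n_rev <- sample(0:3, 1)
    m <- random_model(seed, n_irr = n_irr, n_rev = n_rev)
    sm <- split_reversible(m)
    expect_equal(n_reactions(sm), n_irr + 2 * n_rev)
    expect_false(any(sm$reactions$reversible))
  }
})

test_that("stoichiometric and kinetic-order matrices follow their definitions", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation", "R1\tA -> B", "R2\t2 A -> B"), path)
  m <- read_reaction_table(path)
  mats <- build_matrices(m)
  expect_equal(mats$S[, "R1"], c(A = -1, B = 1))
  expect_equal(mats$A[, "R1"], c(A = 1, B = 0))
  expect_equal(mats$S["A", "R2"], -2)
  expect_equal(mats$A["A", "R2"], 2)

  # reconstruction property on random split models
  for (seed in 6:9) {
    sm <- split_reversible(random_model(seed))
    mats <- build_matrices(sm)
    expect_true(all(mats$A >= 0))
    for (i in seq_len(n_reactions(sm))) {
      re <- sm$reactions$reactants[[i]]
      pr <- sm$reactions$products[[i]]
      col <- stats::setNames(rep(0, n_species(sm)), sm$species$id)
      if (length(pr)) col[names(pr)] <- col[names(pr)] + pr
      if (length(re)) col[names(re)] <- col[names(re)] - re
      expect_equal(mats$S[, i], col)
      acol <- stats::setNames(rep(0, n_species(sm)), sm$species$id)
      if (length(re)) acol[names(re)] <- re
      expect_equal(mats$A[, i], acol)
    }
  }
  expect_error(build_matrices(random_model(1, n_rev = 1)),
               class = "kin_validation_error")
})

test_that("missing concentrations fall back to the mean of listed values", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation", "R1\tA + B -> C"), path)
  m <- read_reaction_table(path)
  m2 <- set_concentrations(m, c(A = 1, B = 3))
  conc <- stats::setNames(m2$species$initial_concentration, m2$species$id)
  expect_equal(conc[["C"]], 2)
  expect_equal(conc[["A"]], 1)

  # all species listed: no substitution
  m3 <- set_concentrations(m, c(A = 1, B = 3, C = 7))
  expect_equal(m3$species$initial_concentration, c(1, 3, 7))

  expect_error(set_concentrations(m, c(A = -1, B = 1)),
               class = "kin_validation_error")
  expect_error(set_concentrations(m, c(A = 1, B = 1), clamped = "ZZZ"),
               class = "kin_validation_error")

  m4 <- set_concentrations(m, c(A = 1, B = 1), clamped = c("A"))
  expect_equal(m4$species$clamped, c(TRUE, FALSE, FALSE))
})

test_that("SBML documents are read with flags, concentrations and reversibility", {
  path <- write_sbml_fixture()
  m <- read_sbml_model(path)
  expect_equal(n_species(m), 4)
  expect_equal(n_reactions(m), 3)
  sp <- m$species
  expect_true(sp$clamped[sp$id == "glc_e"])      # boundaryCondition
  expect_false(sp$internal[sp$id == "glc_e"])
  expect_false(sp$internal[sp$id == "pyr_e"])    # external compartment
  expect_true(sp$internal[sp$id == "glc_c"])
  expect_equal(sp$initial_concentration[sp$id == "glc_e"], 5)
  expect_equal(m$reactions$reversible, c(FALSE, TRUE, FALSE))
  expect_equal(m$reactions$products[[2]], c(pyr_c = 2))

  sm <- split_reversible(m)
  expect_equal(n_reactions(sm), 4)  # 2 irreversible + 2 from the split pair
  expect_true("PGM_reverse" %in% sm$reactions$id)

  bad <- tempfile(fileext = ".xml")
  writeLines("<sbml><model></sbml>", bad)
  expect_error(read_sbml_model(bad), class = "kin_parse_error")
})

test_that("concentration tables and clamped lists load from disk", {
  cpath <- tempfile(fileext = ".tsv")
  writeLines(c("species_id\tconcentration", "A\t1.5", "B\t0"), cpath)
  tbl <- read_concentration_table(cpath)
  expect_equal(tbl$concentration, c(1.5, 0))
  lpath <- tempfile()
  writeLines(c("A", "", "B "), lpath)
  expect_equal(read_clamped_list(lpath), c("A", "B"))
})
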