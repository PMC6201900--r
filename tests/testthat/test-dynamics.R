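two_species_model <- function(clamped_A = FALSE) {
  metabolic_model(
    species = tibble::tibble(id = c("A", "B"), internal = TRUE,
                             clamped = c(clamped_A, FALSE),
                             initial_concentration = c(1, 0)),
    reactions = tibble::tibble(id = "R1", reversible = FALSE,
                               reactants = list(c(A = 1)),
                               products = list(c(B = 1)))
  )
}

test_that("the mass-action rate law follows its definition", {
  m <- two_species_model()
  rate <- build_rate_law(m, k = 1)
  expect_equal(rate(c(2, 0)), 2)              # v = k * x_A
  S <- attr(rate, "matrices")$S
  expect_equal(as.vector(S %*% rate(c(2, 0))), c(-2, 2))

  # second-order reactant: 2A -> B with k = 2 at x_A = 3 gives 2 * 3^2
  m2 <- metabolic_model(
    tibble::tibble(id = c("A", "B"), initial_concentration = c(3, 0)),
    tibble::tibble(id = "R1", reversible = FALSE,
                   reactants = list(c(A = 2)), products = list(c(B = 1)))
  )
  expect_equal(build_rate_law(m2, 2)(c(3, 0)), 18)

  # empty reactant side: constant supply at rate k
  m3 <- metabolic_model(
    tibble::tibble(id = "A"),
    tibble::tibble(id = "R1", reversible = FALSE,
                   reactants = list(stats::setNames(numeric(0), character(0))),
                   products = list(c(A = 1)))
  )
  expect_equal(build_rate_law(m3, 3)(0), 3)

  # negative concentrations are clipped, not propagated
  expect_equal(build_rate_law(m, 1)(c(-0.5, 0)), 0)
  expect_error(build_rate_law(m, c(1, 2)), class = "kin_validation_error")
  expect_error(build_rate_law(m, -1), class = "kin_validation_error")
})

test_that("simulated decay matches the closed-form solution", {
  m <- two_species_model()
  traj <- simulate_dynamics(m, k = 1, t_end = 10, rtol = 1e-8, atol = 1e-12)
  analytic <- exp(-traj$times)
  got <- traj$concentrations[, "A"]
  expect_lt(max(abs(got - analytic) / pmax(analytic, 1e-12)), 1e-6)
  # mass conservation in the closed system
  expect_lt(max(abs(rowSums(traj$concentrations) - 1)), 1e-6)
})

test_that("zero kinetics freeze the trajectory and clamping is bit-exact", {
  m <- two_species_model()
  traj <- simulate_dynamics(m, k = 0, t_end = 5)
  expect_true(all(traj$concentrations[, "A"] == 1))
  expect_true(all(traj$concentrations[, "B"] == 0))

  mc <- two_species_model(clamped_A = TRUE)
  traj <- simulate_dynamics(mc, k = 1, t_end = 5)
  expect_identical(unique(traj$concentrations[, "A"]), 1)  # bit-exact clamp
  # B grows linearly at rate k * A = 1
  expect_lt(max(abs(traj$concentrations[, "B"] - traj$times)), 1e-4)
})

test_that("chain trajectories match the analytic fixed point", {
  ch <- make_linear_chain(3, x0 = 2, k = c(1.2, 0.8, 2.5, 1.1))
  traj <- simulate_dynamics(ch$model, ch$k)
  fs <- final_state(traj)
  expect_lt(max(abs(fs[names(ch$steady_state)] - ch$steady_state) /
                  ch$steady_state), 1e-6)

  # the transient of the first species follows its linear-ODE closed form
  ch1 <- make_linear_chain(1, x0 = 1, k = c(2, 4))
  traj1 <- simulate_dynamics(ch1$model, ch1$k, t_end = 5,
                             rtol = 1e-8, atol = 1e-12)
  analytic <- (2 / 4) * (1 - exp(-4 * traj1$times))
  expect_lt(max(abs(traj1$concentrations[, "X1"] - analytic)), 1e-6)
})

test_that("the steady-state statistic matches a direct computation", {
  # constant trajectory: statistic exactly 0
  m <- two_species_model()
  traj <- simulate_dynamics(m, k = 0, t_end = 100)
  rep <- check_steady_state(traj)
  expect_equal(rep$statistic, 0)
  expect_true(rep$passed)

  # one species ramping with slope 1, one constant, M - S = 2:
  # statistic must equal sd(ramp over the window) / 2
  times <- seq(0, 100, length.out = 1001)
  conc <- cbind(A = times, B = rep(1, length(times)))
  traj2 <- structure(list(
    times = times, concentrations = conc,
    species = tibble::tibble(id = c("A", "B"), internal = TRUE,
                             clamped = FALSE,
                             initial_concentration = c(0, 1)),
    parametrization_id = NA_integer_, condition_id = NA_character_
  ), class = "kin_trajectory")
  rep2 <- check_steady_state(traj2, theta = 0.001)
  window_vals <- times[times >= 90]
  direct_sigma <- sqrt(sum((window_vals - mean(window_vals))^2) /
                         (length(window_vals) - 1))
  expect_equal(rep2$statistic, direct_sigma / 2)
  expect_false(rep2$passed)

  # excluded species contribute zero and shrink the denominator
  traj3 <- traj2
  traj3$species$clamped <- c(TRUE, FALSE)
  rep3 <- check_steady_state(traj3)
  expect_equal(rep3$statistic, 0)

  # window must hold at least 3 points
  traj4 <- traj2
  traj4$times <- c(0, 50, 100)
  traj4$concentrations <- conc[c(1, 500, 1001), ]
  expect_error(check_steady_state(traj4), class = "kin_criterion_error")
})

test_that("a chain with a dead downstream step never reaches steady state", {
  ch <- make_linear_chain(1, x0 = 1, k = c(1, 0))
  expect_null(ch$steady_state)
  traj <- simulate_dynamics(ch$model, ch$k)
  rep <- check_steady_state(traj)
  expect_false(rep$passed)          # X1 accumulates linearly
  expect_gt(rep$statistic, 0.1)
})

test_that("flux-balance residuals shrink as theta tightens", {
  set.seed(99)
  residuals_at <- list()
  runs <- lapply(1:25, function(i) {
    k <- runif(4, 0.2, 3)
    ch <- make_linear_chain(3, x0 = 1, k = k)
    # mixed horizons so some runs are caught mid-transient
    t_end <- sample(c(5, 30, 100), 1)
    traj <- simulate_dynamics(ch$model, k, t_end = t_end)
    list(stat = check_steady_state(traj)$statistic,
         res = steady_state_residual(ch$model, k, traj))
  })
  stats <- vapply(runs, `[[`, numeric(1), "stat")
  res <- vapply(runs, `[[`, numeric(1), "res")
  thetas <- c(1e-2, 1e-3, 1e-4)
  passing <- lapply(thetas, function(th) which(stats < th))
  # nested passing sets, all non-empty at these scales
  expect_true(all(lengths(passing) > 0))
  expect_true(all(passing[[2]] %in% passing[[1]]))
  expect_true(all(passing[[3]] %in% passing[[2]]))
  worst <- vapply(passing, function(idx) max(res[idx]), numeric(1))
  expect_true(all(diff(worst) <= 0))      # tighter theta, smaller residual
  expect_lt(worst[2], 1e-2)               # theta = 1e-3 certifies small residual
})

test_that("relative steady-state mode normalizes by the window mean", {
  ch <- make_linear_chain(2, x0 = 1, k = c(1, 1, 1))
  traj <- simulate_dynamics(ch$model, ch$k, t_end = 8)  # still relaxing
  abs_rep <- check_steady_state(traj)
  rel_rep <- check_steady_state(traj, relative = TRUE)
  expect_false(isTRUE(all.equal(abs_rep$statistic, rel_rep$statistic)))
  expect_equal(glance(rel_rep)$relative, TRUE)
})
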