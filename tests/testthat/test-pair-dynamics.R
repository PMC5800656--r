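test_that("force of infection matches hand-evaluated cases", {
  mom <- spatial_moments(0.5, 0.3)
  p <- fig_params()
  # disease-free
  expect_identical(force_of_infection(pair_state(0, 0, 0),
                                      strain_rates(virus_strain(0), p), mom), 0)
  # purely global: phi = beta_G * x_I
  r1 <- strain_rates(virus_strain(1), p)
  expect_equal(force_of_infection(pair_state(0.4, 0, 0), r1, mom), 4)
  # purely local: phi = beta_L (1 - theta) p_SI / x_S = 7.5 * 0.1 / 0.4
  r0 <- strain_rates(virus_strain(0), p)
  expect_equal(force_of_infection(pair_state(0.1, 0.1, 0), r0, mom), 1.875)
  expect_error(
    force_of_infection(pair_state(0.5, 0.01, 0), r0, mom), "inconsistent")
})

test_that("strain rates respect the theta partition of local transmission", {
  p <- fig_params()
  for (G in c(0, 0.3, 0.8)) {
    r <- strain_rates(virus_strain(G), p)
    expect_equal(r$g, 10 * G)
    expect_equal(r$l / r$psi, (1 - p$theta) / p$theta)
    expect_equal(r$l + r$psi, p$beta_L * (1 - G))
  }
  expect_equal(strain_rates(virus_strain(1), p)$psi, 0)
})

test_that("the disease-free state and frozen dynamics are equilibria", {
  mom <- headline_moments()
  p <- fig_params()
  r <- strain_rates(virus_strain(0.6), p)
  expect_equal(unname(deriv_single(c(0, 0, 0), r, p, mom)), c(0, 0, 0))
  # no recovery and no transmission: any feasible state is frozen
  p0 <- epidemic_params(0, 0, 0)
  r0 <- strain_rates(virus_strain(0.6), p0)
  expect_equal(unname(deriv_single(c(0.1, 0.02, 0.03), r0, p0, mom)),
               c(0, 0, 0))
})

test_that("the closed-form completely-global equilibrium annihilates the derivative", {
  p <- epidemic_params(10, 10, 1)
  mom <- headline_moments()
  eq <- global_strain_equilibrium(p, mom)
  d <- deriv_single(eq$state, strain_rates(virus_strain(1), p), p, mom)
  expect_lt(max(abs(d)), 1e-10)
})

test_that("two-strain dynamics degenerate correctly when one block is absent", {
  p <- fig_params()
  mom <- headline_moments()
  res <- virus_strain(0.7); mut <- virus_strain(0.2)
  y1 <- c(x_I = 0.2, p_SI = 0.05, p_IO = 0.04)
  # no mutants: resident rows reduce to the single-strain equations
  d2 <- deriv_two_strain(c(y1, 0, 0, 0, 0), res, mut, p, mom)
  d1 <- deriv_single(y1, strain_rates(res, p), p, mom)
  expect_equal(unname(d2[1:3]), unname(d1))
  expect_equal(unname(d2[4:7]), c(0, 0, 0, 0))
  # no residents: mutant rows reduce to the single-strain form (phi = 0)
  yJ <- c(x_J = 0.2, p_SJ = 0.05, p_JJ = 0.06)
  p_JO <- yJ[[1]] - yJ[[2]] - yJ[[3]]
  d2 <- deriv_two_strain(c(0, 0, 0, yJ[[1]], yJ[[2]], 0, yJ[[3]]),
                         res, mut, p, mom)
  d1 <- deriv_single(c(yJ[[1]], yJ[[2]], p_JO), strain_rates(mut, p), p, mom)
  expect_equal(unname(d2[["x_J"]]), unname(d1[["x_I"]]))
  expect_equal(unname(d2[["p_SJ"]]), unname(d1[["p_SI"]]))
  # implied d p_JO/dt must match the single-strain p_IO equation
  expect_equal(unname(d2[["x_J"]] - d2[["p_SJ"]] - d2[["p_IJ"]] - d2[["p_JJ"]]),
               unname(d1[["p_IO"]]))
})

test_that("relabelling part of the resident as an identical mutant changes nothing", {
  p <- fig_params()
  mom <- headline_moments()
  G <- 0.4
  eq <- endemic_equilibrium(virus_strain(G), p, mom)
  y0 <- 0.6 * eq$state  # a genuine transient, not the equilibrium
  pII0 <- y0[[1]] - y0[[2]] - y0[[3]]
  split <- c(y0[[1]] / 2, y0[[2]] / 2, y0[[3]] / 2,
             y0[[1]] / 2, y0[[2]] / 2, pII0 / 4, pII0 / 4)
  times <- seq(0, 10, 1)
  tr2 <- integrate_pair_dynamics(split, times, virus_strain(G), p, mom,
                                 mutant = virus_strain(G))
  tr1 <- integrate_pair_dynamics(y0, times, virus_strain(G), p, mom)
  expect_lt(max(abs(tr2$x_I + tr2$x_J - tr1$x_I)), 1e-9)
  expect_lt(max(abs(tr2$p_SI + tr2$p_SJ - tr1$p_SI)), 1e-9)
  expect_lt(max(abs(tr2$p_IO + tr2$p_JO - tr1$p_IO)), 1e-9)
})

test_that("integrated trajectories conserve the pair budgets", {
  set.seed(23)
  for (i in 1:5) {
    d <- draw_params(endemic_margin = 0.5)
    tr <- integrate_pair_dynamics(
      seed_state_for_test(d$moments), seq(0, 30, 2),
      virus_strain(d$G), d$params, d$moments)
    expect_lte(max(conservation_residuals(tr)), 1e-8)
    expect_true(all(tr[, c("x_I", "p_SI", "p_IO", "x_S", "p_II", "p_SS",
                           "p_SO")] >= 0))
  }
})

test_that("integration from a seeded infection reaches the closed-form equilibrium", {
  p <- epidemic_params(10, 10, 1)
  mom <- headline_moments()
  tr <- integrate_pair_dynamics(seed_state_for_test(mom), c(0, 200),
                                virus_strain(1), p, mom)
  final <- unlist(tr[nrow(tr), c("x_I", "p_SI", "p_IO")])
  expect_equal(unname(final), unname(global_strain_equilibrium(p, mom)$state),
               tolerance = 1e-7)
})

test_that("reconstruction rejects states that break the invariants", {
  mom <- headline_moments()
  expect_error(reconstruct_single(c(0.1, 0.2, 0.05), mom), "negative density")
  expect_error(reconstruct_two(c(0.3, 0.01, 0.01, 0.3, 0.01, 0.01, 0.01),
                               spatial_moments(0.5, 0.1)), "negative density")
  # tiny undershoot is floored, not fatal
  out <- reconstruct_single(c(-1e-12, 0, 0), mom)
  expect_identical(out[["x_I"]], 0)
})
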