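test_that("closed-form R0 reduces to the single-mode quantities", {
  # completely global: R0 = beta_G x_C / alpha
  p <- epidemic_params(10, 10, 4)
  r0 <- basic_reproduction_number(virus_strain(1), p, spatial_moments(0.5, 0.25))
  expect_equal(as.numeric(r0), 1.25)
  expect_equal(attr(r0, "rho1"), 1.25)
  # completely local: R0 = beta_L (1 - theta) q_C/C / alpha
  p <- epidemic_params(10, 10, 1)
  r0 <- basic_reproduction_number(virus_strain(0), p, spatial_moments(0.5, 0.4))
  expect_equal(as.numeric(r0), 6)
  expect_equal(attr(r0, "rho0"), 6)
  # no transmission at all
  p0 <- epidemic_params(0, 0, 1)
  expect_equal(as.numeric(
    basic_reproduction_number(virus_strain(0.5), p0, spatial_moments(0.5, 0.25))), 0)
  expect_error(basic_reproduction_number(
    virus_strain(1), epidemic_params(10, 10, 0), spatial_moments(0.5, 0.25)),
    "alpha")
})

test_that("next-generation-matrix R0 matches the closed form on random draws", {
  set.seed(101)
  for (i in 1:50) {
    d <- draw_params()
    s <- virus_strain(d$G)
    expect_equal(r0_via_ngm(s, d$params, d$moments),
                 as.numeric(basic_reproduction_number(s, d$params, d$moments)),
                 tolerance = 1e-10)
  }
  # special cases: purely global equals rho1; zero transmission gives 0
  p <- epidemic_params(7, 3, 2)
  mom <- spatial_moments(0.6, 0.4)
  expect_equal(r0_via_ngm(virus_strain(1), p, mom), 7 * 0.6 / 2,
               tolerance = 1e-10)
  expect_equal(r0_via_ngm(virus_strain(0.5), epidemic_params(0, 0, 2), mom), 0)
})

test_that("the quadratic endemic condition matches hand-worked thresholds", {
  mom <- spatial_moments(0.5, 0.25)
  # G = 1: threshold at alpha = beta_G x_C = 5
  e <- is_endemic(virus_strain(1), epidemic_params(10, 10, 5.5), mom)
  expect_false(e$endemic)
  expect_equal(e$margin, 5.5^2 - 5.5 * 5)
  expect_true(is_endemic(virus_strain(1), epidemic_params(10, 10, 4), mom)$endemic)
  # vanishing recovery: always endemic when transmission is positive
  expect_true(is_endemic(virus_strain(0.5), epidemic_params(10, 10, 1e-6),
                         mom)$endemic)
})

test_that("endemic condition, rho form and R0 > 1 agree on random draws", {
  set.seed(202)
  for (i in 1:50) {
    d <- draw_params()
    e <- is_endemic(virus_strain(d$G), d$params, d$moments)
    if (abs(e$margin) < 1e-10) next  # boundary ties excluded
    expect_identical(e$endemic, e$r0 > 1)
    if (!is.na(e$rho_form)) expect_identical(e$endemic, e$rho_form)
  }
})

test_that("R0 is non-increasing in the recovery rate", {
  mom <- spatial_moments(0.5, 0.35)
  alphas <- seq(0.5, 6, by = 0.5)
  for (G in c(0, 0.4, 1)) {
    r0s <- vapply(alphas, function(a)
      as.numeric(basic_reproduction_number(virus_strain(G),
                                           epidemic_params(10, 10, a), mom)),
      numeric(1))
    expect_true(all(diff(r0s) <= 1e-12))
  }
})

test_that("numerical steady state reproduces the completely-global closed form", {
  p <- epidemic_params(10, 10, 1)
  mom <- headline_moments()
  eq_num <- endemic_equilibrium(virus_strain(1), p, mom)
  expect_false(eq_num$extinct)
  expect_equal(unname(eq_num$state), c(0.4, 0.048, 0.16), tolerance = 1e-8)
  # boundary: alpha = beta_G x_C gives a vanishing infected density
  eqb <- global_strain_equilibrium(epidemic_params(10, 10, 5), mom)
  expect_identical(unname(eqb$state), c(0, 0, 0))
  expect_true(eqb$extinct)
})

test_that("non-endemic parameters yield extinction, also under integration", {
  p <- epidemic_params(10, 10, 5.5)
  mom <- spatial_moments(0.5, 0.25)
  eq <- endemic_equilibrium(virus_strain(1), p, mom)
  expect_true(eq$extinct)
  tr <- integrate_pair_dynamics(seed_state_for_test(mom), c(0, 100),
                                virus_strain(1), p, mom)
  expect_lt(tr$x_I[nrow(tr)], 1e-6)
})

test_that("the steady state is insensitive to the seeded infection", {
  p <- fig_params()
  mom <- headline_moments()
  s <- virus_strain(0.35)
  eq1 <- endemic_equilibrium(s, p, mom, init_frac = 0.01)
  eq2 <- endemic_equilibrium(s, p, mom, init_frac = 0.4)
  expect_equal(eq1$state, eq2$state, tolerance = 1e-9)
  expect_lt(eq1$max_deriv, 1e-9)
})
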