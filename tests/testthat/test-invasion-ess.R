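test_that("self-invasion is neutral across trait values", {
  p <- fig_params()
  mom <- headline_moments()
  for (G in c(0, 0.25, 0.5, 0.75, 1)) {
    lam <- invasion_growth_rate(G, G, p, mom)
    expect_lt(abs(lam), 1e-8)
    expect_false(can_invade(G, G, p, mom))
  }
})

test_that("the analytic mutant Jacobian matches finite differences of the full system", {
  p <- fig_params()
  mom <- headline_moments()
  for (gg in list(c(0.8, 0.3), c(0.2, 0.9), c(1, 0.5))) {
    res <- virus_strain(gg[1]); mut <- virus_strain(gg[2])
    eq <- endemic_equilibrium(res, p, mom)
    M_analytic <- pairsis:::mutant_jacobian(res, mut, p, mom, eq)
    full <- function(z) {
      y <- c(eq$state, z)
      unname(deriv_two_strain(y, res, mut, p, mom, guard = FALSE)[4:7])
    }
    M_fd <- pracma::jacobian(full, c(0, 0, 0, 0))
    expect_equal(M_analytic, M_fd, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("invasion of a non-endemic resident is refused with guidance", {
  p <- epidemic_params(10, 10, 6)
  expect_error(invasion_growth_rate(1, 0.5, p, spatial_moments(0.5, 0.25)),
               "not endemic")
})

test_that("numerical invasion of the completely global strain matches the closed form", {
  set.seed(77)
  grid <- strain_grid(21L)
  mutants <- grid$G[grid$G < 1]
  n_checked <- 0
  while (n_checked < 20) {
    beta_G <- runif(1, 2, 15); beta_L <- runif(1, 2, 15)
    alpha <- runif(1, 0.3, 3)
    x_C <- runif(1, 0.25, 0.9)
    p <- epidemic_params(beta_G, beta_L, alpha)
    if (beta_G * x_C <= alpha * 1.05) next  # resident must be endemic
    mom <- spatial_moments(x_C, runif(1, 0.2 * x_C, x_C))
    eq <- endemic_equilibrium(virus_strain(1), p, mom)
    num <- vapply(mutants, function(gp)
      can_invade(virus_strain(1), virus_strain(gp), p, mom, eq), logical(1))
    closed <- vapply(mutants, function(gp)
      invades_global_strain(gp, p, mom), logical(1))
    expect_identical(num, closed)
    n_checked <- n_checked + 1
  }
})

test_that("the completely-global ESS threshold sits at beta_G / beta_L", {
  # equal rates: protection exactly up to complete spatial randomness
  p <- fig_params()
  x_C <- 0.5
  clustered <- spatial_moments(x_C, 1.2 * x_C^2)
  dispersed <- spatial_moments(x_C, 0.8 * x_C^2)
  expect_true(invades_global_strain(0.99, p, clustered))
  expect_false(invades_global_strain(0.99, p, dispersed))
  # the G' -> 1 threshold moves with the rate ratio
  p2 <- epidemic_params(8, 10, 1)
  expect_true(invades_global_strain(0.999, p2, spatial_moments(x_C, 0.81 * x_C^2)))
  expect_false(invades_global_strain(0.999, p2, spatial_moments(x_C, 0.79 * x_C^2)))
  # a completely local mutant needs much stronger clustering: 4/3 at equal rates
  expect_false(invades_global_strain(0, p, spatial_moments(x_C, 1.3 * x_C^2)))
  expect_true(invades_global_strain(0, p, spatial_moments(x_C, 0.345)))  # 1.38
})

test_that("a moderately clustered lattice selects an intermediate ESS", {
  pip <- build_pip(strain_grid(26L), fig_params(), headline_moments())
  expect_false(any(is.na(pip$invade)))
  expect_false(any(diag(pip$invade)))
  ess_rows <- pip$singular[pip$singular$type == "ESS", ]
  expect_identical(nrow(ess_rows), 1L)
  expect_gt(ess_rows$G, 0.4)
  expect_lt(ess_rows$G, 0.8)
  ess <- find_local_ess(strain_grid(26L), fig_params(), headline_moments(),
                        pip = pip)
  expect_identical(ess, ess_rows$G)
})

test_that("over-dispersed lattices make complete global infection the ESS", {
  grid <- strain_grid(26L)
  ess <- find_local_ess(grid, fig_params(), spatial_moments(0.5, 0.2))
  expect_identical(ess, 1)
})

test_that("the square-root trade-off produces bistability with a repeller", {
  grid <- strain_grid(51L)
  pip <- build_pip(grid, fig_params(), spatial_moments(0.5, 0.4),
                   tradeoff_exponent = 0.5)
  expect_true("repeller" %in% pip$singular$type)
  rep_G <- pip$singular$G[pip$singular$type == "repeller"]
  expect_gt(rep_G, 0.25)
  expect_lt(rep_G, 0.55)
  # both extremes are protected boundary attractors
  ess <- find_local_ess(grid, fig_params(), spatial_moments(0.5, 0.4),
                        tradeoff_exponent = 0.5, pip = pip)
  expect_true(all(c(0, 1) %in% ess))
})

test_that("R0 maximization departs from the ESS under strong clustering", {
  grid <- strain_grid(101L)
  p <- fig_params()
  # no local route at all: maximum must sit at complete global infection
  expect_identical(as.numeric(r0_maximizing_G(grid, epidemic_params(10, 0, 1),
                                              headline_moments())), 1)
  # strong clustering: interior R0 maximizer, ESS well below it
  mom <- spatial_moments(0.5, 0.375)  # clustering 1.5
  gmax <- as.numeric(r0_maximizing_G(grid, p, mom))
  expect_gt(gmax, 0)
  expect_lt(gmax, 1)
  ess <- find_local_ess(strain_grid(26L), p, mom)
  expect_lt(max(ess), gmax)
})

test_that("the clustering scan localizes the invasion threshold", {
  p <- fig_params()
  thr <- scan_global_ess_threshold(p, 0.5, c(0.24, 0.27), p_CC_step = 0.0025,
                                   grid = strain_grid(51L))
  expect_lt(abs(thr - 1), 0.02)
  scan <- attr(thr, "scan")
  # invadability is monotone in the scanned clustering
  expect_true(all(diff(scan$invadable) >= 0))
})
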