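test_that("a lattice with no infected cells only advances the clock", {
  st <- mc_state(generate_csr(0.5, c(20L, 20L), seed = 1), G = 0.5,
                 initial_infected_fraction = 0)
  out <- mc_step(st, fig_params(), dt = 0.005)
  expect_identical(out$site_state, st$site_state)
  expect_equal(out$time, 0.005)
})

test_that("without recovery every target cell is eventually infected", {
  st <- uniform_structure(c(15L, 15L))
  p <- epidemic_params(10, 10, 0)
  s <- mc_state(st, G = 0.5, initial_infected_fraction = 0.05, seed = 2)
  run <- pairsis:::mc_run_core(s, p, dt = 0.005, nsteps = 2000L, mu = 0,
                               record_every_steps = 200L)
  expect_equal(sum(run$state$site_state > 0), 15L * 15L)
})

test_that("oversized steps are rejected with a demand for smaller dt", {
  st <- mc_state(uniform_structure(c(10L, 10L)), G = 0,
                 initial_infected_fraction = 0.5, seed = 3)
  expect_error(mc_step(st, fig_params(), dt = 0.5), "reduce dt")
})

test_that("the target/non-target mask is frozen over a run", {
  lat <- generate_csr(0.5, c(25L, 25L), seed = 4)
  res <- run_evolution(lat, strain_grid(11L), fig_params(),
                       mc_config(t_end = 5, seed = 5))
  expect_true(attr(res, "dt_used") <= 0.05)
  s0 <- mc_state(lat, strain_grid(11L))
  expect_identical(s0$site_state < 0, !lat$mask)
})

test_that("identical configuration and seed reproduce the trajectory exactly", {
  lat <- generate_csr(0.5, c(20L, 20L), seed = 6)
  cfg <- mc_config(t_end = 10, seed = 99)
  t1 <- run_evolution(lat, strain_grid(11L), fig_params(), cfg)
  t2 <- run_evolution(lat, strain_grid(11L), fig_params(), cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "strain_counts"), attr(t2, "strain_counts"))
})

test_that("without mutation no new strains ever appear", {
  lat <- generate_csr(0.5, c(20L, 20L), seed = 7)
  cfg <- mc_config(t_end = 20, mu = 0, seed = 8)
  tr <- run_evolution(lat, strain_grid(11L), fig_params(), cfg, init_G = 0.5)
  counts <- attr(tr, "strain_counts")
  started <- which(colSums(counts) > 0)
  expect_identical(started, which(strain_grid(11L)$G == 0.5))
})

test_that("with mutation the trait distribution spreads to adjacent strains", {
  lat <- generate_csr(0.5, c(20L, 20L), seed = 9)
  cfg <- mc_config(t_end = 30, mu = 0.05, seed = 10)
  tr <- run_evolution(lat, strain_grid(11L), fig_params(), cfg, init_G = 0.5)
  counts <- attr(tr, "strain_counts")
  expect_gt(sum(colSums(counts) > 0), 1L)
})

test_that("survival is non-increasing in the recovery rate", {
  lat <- generate_csr(0.5, c(25L, 25L), seed = 11)
  surv <- vapply(c(1, 4.5, 8), function(a) {
    run_persistence(lat, 1, fig_params(alpha = a),
                    mc_config(t_end = 60, n_replicates = 6, seed = 12))$survival_fraction
  }, numeric(1))
  expect_true(all(diff(surv) <= 0.35))  # stochastic slack on 6 replicates
  expect_gt(surv[1], surv[3])
})

test_that("stochastic equilibrium agrees with the pair approximation for global spread", {
  lat <- generate_csr(0.5, c(40L, 40L), seed = 13)
  p <- fig_params()
  xhat <- global_strain_equilibrium(p, measure_moments(lat))$state[["x_I"]]
  cfg <- mc_config(t_end = 50, seed = 14)
  means <- vapply(1:4, function(r) {
    tr <- run_evolution(lat, strain_grid(2L), p,
                        mc_config(t_end = 50, mu = 0, seed = 14 + r),
                        init_G = 1)
    tail <- tr[tr$time >= 20, ]
    mean(tail$infected_density)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - xhat), 3 * se + 0.01)
})

test_that("trajectory summaries are exact on hand-made series", {
  const <- data.frame(time = 0:10, mean_G = rep(0.4, 11))
  s <- summarize_trajectory(const, 0.5)
  expect_equal(unname(s[c("mean_G", "sd_G")]), c(0.4, 0))
  alt <- data.frame(time = 0:9, mean_G = rep(c(0.2, 0.6), 5))
  s <- summarize_trajectory(alt, 1)
  expect_equal(unname(s[["mean_G"]]), 0.4)
  expect_equal(unname(s[["sd_G"]]), sd(rep(c(0.2, 0.6), 5)))
  expect_error(summarize_trajectory(data.frame(time = 0, mean_G = 1), 0.5),
               "shorter")
})
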