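#' Monte-Carlo simulation settings
#'
#' Fixed-step synchronous updates with exponential per-event probabilities.
#' `dt` is automatically reduced so that no per-site event probability can
#' exceed 0.1 in one step (the bound uses the largest attainable hazard:
#' full global pressure at the lattice's target density plus full local
#' pressure from four infected neighbors).
#'
#' @param dt requested step size (default 0.05; reduced if the probability
#'   cap binds).
#' @param t_end simulation horizon (time units).
#' @param n_replicates independent replicate runs where applicable.
#' @param initial_infected_fraction fraction of target cells initially
#'   infected (default 0.1).
#' @param mu mutation probability per transmission event (default 0.01).
#' @param seed optional integer seed.
#' @param record_every record the state every this many time units
#'   (default 1).
#' @export
mc_config <- function(dt = 0.05, t_end = 500, n_replicates = 20,
                      initial_infected_fraction = 0.1, mu = 0.01,
                      seed = NULL, record_every = 1) {
  stopifnot(dt > 0, t_end > 0, n_replicates >= 1,
            initial_infected_fraction > 0, initial_infected_fraction <= 1,
            mu >= 0, mu <= 1, record_every > 0)
  structure(list(dt = dt, t_end = t_end, n_replicates = n_replicates,
                 initial_infected_fraction = initial_infected_fraction,
                 mu = mu, seed = seed, record_every = record_every),
            class = "mc_config")
}

# Step size respecting the 0.1 per-event probability cap. Hazard bound:
# global pressure if every target cell carried the most global strain, plus
# local pressure from four fully local neighbors; recovery bounded by alpha.
mc_choose_dt <- function(dt, params, structure, G, tradeoff_s) {
  x_frac <- sum(structure$mask) / (structure$height * structure$width)
  h_bound <- max(params$beta_G * G) * x_frac +
    max(params$beta_L * local_weight(G, tradeoff_s))
  cap <- 0.1
  dt_max <- cap / max(h_bound, params$alpha, 1e-12)
  min(dt, dt_max)
}

#' Concrete lattice epidemic state
#'
#' Pairs a [spatial_structure()] with a per-site state (susceptible or
#' infected by one of the registered strains) and a continuous clock. The
#' target/non-target mask is frozen: only target sites change state.
#'
#' @param structure a [spatial_structure()].
#' @param G strain registry: vector of G values (a [strain_grid()] is
#'   accepted).
#' @param tradeoff_exponent trade-off exponent shared by all strains.
#' @param init_strain index (1-based) of the strain carried by the initial
#'   infecteds.
#' @param initial_infected_fraction fraction of target cells infected at
#'   time 0, chosen uniformly at random.
#' @param seed optional integer seed for the initial draw.
#' @export
mc_state <- function(structure, G, tradeoff_exponent = 1, init_strain = 1L,
                     initial_infected_fraction = 0.1, seed = NULL) {
  stopifnot(inherits(structure, "spatial_structure"))
  if (inherits(G, "strain_grid")) G <- G$G
  stopifnot(init_strain >= 1L, init_strain <= length(G))
  stopifnot(initial_infected_fraction >= 0, initial_infected_fraction <= 1)
  site <- matrix(-1L, structure$height, structure$width)
  site[structure$mask] <- 0L
  with_seed(seed, {
    targets <- which(structure$mask)
    n_inf <- round(initial_infected_fraction * length(targets))
    if (initial_infected_fraction > 0) n_inf <- max(1L, n_inf)
    if (n_inf > 0) site[sample(targets, n_inf)] <- as.integer(init_strain)
  })
  structure(list(structure = structure, site_state = site, G = G,
                 tradeoff_exponent = tradeoff_exponent, time = 0),
            class = "mc_state")
}

mc_run_core <- function(state, params, dt, nsteps, mu, record_every_steps,
                        record_strains = FALSE) {
  res <- mc_simulate_cpp(state$site_state, state$G, state$tradeoff_exponent,
                         params$beta_G, params$beta_L, params$alpha, dt,
                         as.integer(nsteps), mu,
                         as.integer(record_every_steps), record_strains)
  traj <- data.frame(time = state$time + res$time,
                     n_infected = res$n_infected, mean_G = res$mean_G)
  new_state <- state
  new_state$site_state <- res$state
  new_state$time <- state$time + nsteps * dt
  list(state = new_state, trajectory = traj,
       strain_counts = res$strain_counts, extinct = res$extinct,
       t_extinct = if (res$extinct) state$time + res$t_extinct else NA_real_)
}

#' Advance a lattice state by one synchronous step
#'
#' One fixed-interval update: every susceptible target cell is exposed to
#' the summed global hazard of all strains plus the local hazard of its four
#' neighbors and infected with probability 1 - exp(-h dt) (strain chosen
#' proportional to its hazard contribution, mutating to an adjacent-G strain
#' with probability `mu`); every infected cell recovers with probability
#' 1 - exp(-alpha dt). All probabilities use the state at the start of the
#' step.
#'
#' @param state an [mc_state()].
#' @param params an [epidemic_params()].
#' @param dt step size; must respect the 0.1 event-probability cap or an
#'   error demands a smaller step.
#' @param mu mutation probability per transmission.
#' @return the updated [mc_state()] (clock advanced by `dt`).
#' @export
mc_step <- function(state, params, dt = 0.01, mu = 0) {
  stopifnot(inherits(state, "mc_state"))
  mc_run_core(state, params, dt, 1L, mu, 1L)$state
}

#' Persistence probability of a single strain
#'
#' Replicated stochastic runs from a seeded initial infection; reports the
#' fraction of replicates with at least one infected cell at `t_end`, plus
#' the per-replicate extinction times.
#'
#' @param structure a [spatial_structure()].
#' @param strain_G proportion of global infection of the focal strain.
#' @param params an [epidemic_params()].
#' @param config an [mc_config()] (`t_end` default 500, `n_replicates` 20).
#' @param tradeoff_exponent trade-off exponent.
#' @return list: `survival_fraction`, `extinction_times` (NA where the virus
#'   persisted), `dt_used`.
#' @export
run_persistence <- function(structure, strain_G, params,
                            config = mc_config(t_end = 500, n_replicates = 20),
                            tradeoff_exponent = 1) {
  dt <- mc_choose_dt(config$dt, params, structure, strain_G, tradeoff_exponent)
  nsteps <- ceiling(config$t_end / dt)
  rec <- max(1L, floor(config$record_every / dt))
  with_seed(config$seed, {
    ext_times <- rep(NA_real_, config$n_replicates)
    surv <- logical(config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      st <- mc_state(structure, strain_G, tradeoff_exponent,
                     initial_infected_fraction = config$initial_infected_fraction)
      run <- mc_run_core(st, params, dt, nsteps, mu = 0,
                         record_every_steps = rec)
      surv[r] <- !run$extinct
      ext_times[r] <- run$t_extinct
    }
    list(survival_fraction = mean(surv), extinction_times = ext_times,
         dt_used = dt)
  })
}

#' Evolutionary dynamics on a lattice with mutation among grid strains
#'
#' Long stochastic run in which every transmission can mutate the strain to
#' an adjacent G value on the grid. Returns the time series of total
#' infected density and population-mean G, with per-strain densities
#' attached.
#'
#' @param structure a [spatial_structure()].
#' @param grid a [strain_grid()] (101 strains by default upstream).
#' @param params an [epidemic_params()].
#' @param config an [mc_config()]; `t_end` default 5000 in the headline
#'   experiments, `mu` default 0.01.
#' @param init_G initial mean trait: the initial infecteds all carry the
#'   grid strain closest to this value (default 0.5).
#' @param tradeoff_exponent trade-off exponent.
#' @return data.frame of class `mc_trajectory` (time, n_infected, mean_G,
#'   infected_density) with attributes `strain_counts` (records x strains
#'   matrix), `G` (grid values), `extinct`, `t_extinct`, `dt_used`, `n_sites`.
#' @export
run_evolution <- function(structure, grid, params,
                          config = mc_config(t_end = 5000),
                          init_G = 0.5, tradeoff_exponent = 1) {
  stopifnot(inherits(grid, "strain_grid"))
  dt <- mc_choose_dt(config$dt, params, structure, grid$G, tradeoff_exponent)
  nsteps <- ceiling(config$t_end / dt)
  rec <- max(1L, floor(config$record_every / dt))
  with_seed(config$seed, {
    st <- mc_state(structure, grid, tradeoff_exponent,
                   init_strain = which.min(abs(grid$G - init_G)),
                   initial_infected_fraction = config$initial_infected_fraction)
    run <- mc_run_core(st, params, dt, nsteps, mu = config$mu,
                       record_every_steps = rec, record_strains = TRUE)
    n_sites <- structure$height * structure$width
    traj <- run$trajectory
    traj$infected_density <- traj$n_infected / n_sites
    attr(traj, "strain_counts") <- run$strain_counts
    attr(traj, "G") <- grid$G
    attr(traj, "extinct") <- run$extinct
    attr(traj, "t_extinct") <- run$t_extinct
    attr(traj, "dt_used") <- dt
    attr(traj, "n_sites") <- n_sites
    class(traj) <- c("mc_trajectory", "data.frame")
    traj
  })
}

#' Tail-window summary of an evolutionary trajectory
#'
#' Mean and standard deviation of the population-mean trait over the final
#' `tail_fraction` of the recorded time series (the long-term average once
#' the trait distribution has settled).
#'
#' @param trajectory an `mc_trajectory` (or any data.frame with `time` and
#'   `mean_G`).
#' @param tail_fraction fraction of the record, from the end, to average
#'   over (default 0.5).
#' @return named vector `c(mean_G, sd_G, n)`.
#' @export
summarize_trajectory <- function(trajectory, tail_fraction = 0.5) {
  stopifnot(is.data.frame(trajectory), tail_fraction > 0, tail_fraction <= 1)
  t0 <- max(trajectory$time) - tail_fraction * diff(range(trajectory$time))
  tail <- trajectory[trajectory$time >= t0, ]
  if (nrow(tail) < 2L)
    stop("trajectory shorter than the requested tail window")
  g <- tail$mean_G[!is.na(tail$mean_G)]
  if (length(g) == 0L) stop("no surviving records in the tail window")
  c(mean_G = mean(g), sd_G = if (length(g) > 1) sd(g) else 0, n = length(g))
}
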