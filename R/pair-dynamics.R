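#' Single-strain pair-approximation state
#'
#' The three independent variables of the single-strain dynamics: the global
#' infected density x_I (which equals p_SI + p_II + p_IO), the
#' susceptible-infected pair density p_SI, and the infected/non-target pair
#' density p_IO. All other singlet and pair densities follow from the
#' conserved spatial moments:
#' x_S = x_C - x_I, p_II = x_I - p_SI - p_IO,
#' p_SS = p_CC - 2 p_SI - p_II, p_SO = (x_C - p_CC) - p_IO.
#' Pair densities are ordered (each unordered neighbor pair counted from both
#' ends), hence the factor 2 on p_SI in the p_CC budget.
#'
#' @param x_I,p_SI,p_IO non-negative densities.
#' @export
pair_state <- function(x_I, p_SI, p_IO) {
  v <- c(x_I = unname(x_I), p_SI = unname(p_SI), p_IO = unname(p_IO))
  stopifnot(all(is.finite(v)))
  structure(list(x_I = v[["x_I"]], p_SI = v[["p_SI"]], p_IO = v[["p_IO"]]),
            class = "pair_state")
}

as_state_vec <- function(state) {
  if (inherits(state, "pair_state"))
    c(x_I = state$x_I, p_SI = state$p_SI, p_IO = state$p_IO)
  else {
    stopifnot(is.numeric(state), length(state) == 3L)
    setNames(as.numeric(state), c("x_I", "p_SI", "p_IO"))
  }
}

# Floor tiny numerical undershoots; anything below -tol is a real violation.
guard_nonneg <- function(v, tol, what) {
  bad <- v < -tol
  if (any(bad))
    stop(sprintf("negative density beyond tolerance in %s: min = %.3g",
                 what, min(v)))
  pmax(v, 0)
}

#' Reconstruct all densities of a single-strain state
#'
#' @param state a [pair_state()] or numeric `c(x_I, p_SI, p_IO)`.
#' @param moments a [spatial_moments()].
#' @param tol tolerance below which reconstructed densities may undershoot
#'   zero before an error is raised; values within it are floored at 0.
#' @param guard validate and floor negative densities; `FALSE` returns the
#'   raw algebra (used for finite-difference linearizations, whose probe
#'   displacements are deliberately signed).
#' @return named numeric vector with x_I, p_SI, p_IO, x_S, p_II, p_SS, p_SO.
#' @export
reconstruct_single <- function(state, moments, tol = 1e-8, guard = TRUE) {
  y <- as_state_vec(state)
  x_S <- moments$x_C - y[["x_I"]]
  p_II <- y[["x_I"]] - y[["p_SI"]] - y[["p_IO"]]
  p_SS <- moments$p_CC - 2 * y[["p_SI"]] - p_II
  p_SO <- (moments$x_C - moments$p_CC) - y[["p_IO"]]
  out <- c(y, x_S = unname(x_S), p_II = unname(p_II),
           p_SS = unname(p_SS), p_SO = unname(p_SO))
  if (!guard) return(out)
  guard_nonneg(out, tol, "single-strain state reconstruction")
}

#' Force of infection on a susceptible cell
#'
#' phi = g x_I + l p_SI / x_S: the per-susceptible hazard from global
#' transmission by all infected cells plus local transmission from infected
#' neighbors outside a focal pair (the within-pair share psi is accounted
#' separately in the pair equations).
#'
#' @param state a [pair_state()].
#' @param rates output of [strain_rates()].
#' @param moments a [spatial_moments()].
#' @export
force_of_infection <- function(state, rates, moments) {
  y <- as_state_vec(state)
  x_S <- moments$x_C - y[["x_I"]]
  if (x_S <= 0) {
    if (y[["p_SI"]] > 0)
      stop("inconsistent state: p_SI > 0 with no susceptible cells (x_S = 0)")
    return(rates$g * y[["x_I"]])
  }
  rates$g * y[["x_I"]] + rates$l * y[["p_SI"]] / x_S
}

#' Time derivative of the single-strain pair dynamics
#'
#' dx_I/dt = g x_S x_I + (l + psi) p_SI - alpha x_I,
#' dp_SI/dt = -(phi + psi + alpha) p_SI + phi p_SS + alpha p_II,
#' dp_IO/dt = phi p_SO - alpha p_IO,
#' with the dependent densities reconstructed from the conserved moments and
#' triple correlations closed at the pair level
#' (q_sigma/sigma'sigma'' ~ q_sigma/sigma').
#'
#' @inheritParams force_of_infection
#' @param params an [epidemic_params()].
#' @param tol reconstruction tolerance (see [reconstruct_single()]).
#' @param guard see [reconstruct_single()].
#' @return named numeric derivative vector.
#' @export
deriv_single <- function(state, rates, params, moments, tol = 1e-8,
                         guard = TRUE) {
  d <- reconstruct_single(state, moments, tol, guard)
  phi <- if (d[["x_S"]] > 0) rates$g * d[["x_I"]] + rates$l * d[["p_SI"]] / d[["x_S"]]
         else rates$g * d[["x_I"]]
  al <- params$alpha
  c(x_I = rates$g * d[["x_S"]] * d[["x_I"]] +
        (rates$l + rates$psi) * d[["p_SI"]] - al * d[["x_I"]],
    p_SI = -(phi + rates$psi + al) * d[["p_SI"]] + phi * d[["p_SS"]] +
        al * d[["p_II"]],
    p_IO = phi * d[["p_SO"]] - al * d[["p_IO"]])
}

#' Resident-plus-mutant pair-approximation state
#'
#' The seven independent variables of the two-strain dynamics: the resident
#' block (x_I, p_SI, p_IO) and the mutant block (x_J, p_SJ, p_IJ, p_JJ).
#' Dependent densities: x_S = x_C - x_I - x_J,
#' p_II = x_I - p_SI - p_IJ - p_IO, p_JO = x_J - p_SJ - p_IJ - p_JJ,
#' p_SS = p_CC - 2 p_SI - 2 p_SJ - p_II - 2 p_IJ - p_JJ,
#' p_SO = (x_C - p_CC) - p_IO - p_JO. All pair densities are ordered; p_IJ
#' counts (resident, mutant) ordered pairs, so a neutral 50/50 relabelling of
#' an endemic resident splits p_II into p_II/4, p_IJ = p_II/4, p_JJ = p_II/4.
#'
#' @param x_I,p_SI,p_IO resident block.
#' @param x_J,p_SJ,p_IJ,p_JJ mutant block.
#' @export
two_strain_state <- function(x_I, p_SI, p_IO, x_J, p_SJ, p_IJ, p_JJ) {
  v <- c(x_I = x_I, p_SI = p_SI, p_IO = p_IO, x_J = x_J, p_SJ = p_SJ,
         p_IJ = p_IJ, p_JJ = p_JJ)
  stopifnot(all(is.finite(v)))
  structure(as.list(v), class = "two_strain_state")
}

as_state_vec2 <- function(state) {
  nm <- c("x_I", "p_SI", "p_IO", "x_J", "p_SJ", "p_IJ", "p_JJ")
  if (inherits(state, "two_strain_state")) unlist(state)[nm]
  else {
    stopifnot(is.numeric(state), length(state) == 7L)
    setNames(as.numeric(state), nm)
  }
}

#' Reconstruct all densities of a two-strain state
#'
#' @param state a [two_strain_state()] or numeric vector of length 7.
#' @inheritParams reconstruct_single
#' @export
reconstruct_two <- function(state, moments, tol = 1e-8, guard = TRUE) {
  y <- as_state_vec2(state)
  x_S <- moments$x_C - y[["x_I"]] - y[["x_J"]]
  p_II <- y[["x_I"]] - y[["p_SI"]] - y[["p_IJ"]] - y[["p_IO"]]
  p_JO <- y[["x_J"]] - y[["p_SJ"]] - y[["p_IJ"]] - y[["p_JJ"]]
  p_SS <- moments$p_CC - 2 * y[["p_SI"]] - 2 * y[["p_SJ"]] - p_II -
    2 * y[["p_IJ"]] - y[["p_JJ"]]
  p_SO <- (moments$x_C - moments$p_CC) - y[["p_IO"]] - p_JO
  out <- c(y, x_S = unname(x_S), p_II = unname(p_II), p_JO = unname(p_JO),
           p_SS = unname(p_SS), p_SO = unname(p_SO))
  if (!guard) return(out)
  guard_nonneg(out, tol, "two-strain state reconstruction")
}

#' Time derivative of the resident + mutant pair dynamics
#'
#' The seven coupled equations for a resident strain (rates g, l, psi; force
#' phi = g x_I + l p_SI / x_S) and a mutant strain (primed rates; force
#' phi' = g' x_J + l' p_SJ / x_S). The resident SI equation carries the loss
#' term -phi' p_SI matching the phi' p_SI gain of the mixed pair p_IJ, so
#' that relabelling part of a resident population as an identical "mutant"
#' leaves every aggregate trajectory exactly unchanged.
#'
#' @param state a [two_strain_state()] or numeric vector of length 7.
#' @param resident,mutant [virus_strain()] objects (or bare G values).
#' @param params an [epidemic_params()].
#' @param moments a [spatial_moments()].
#' @param tol reconstruction tolerance.
#' @param guard see [reconstruct_single()].
#' @export
deriv_two_strain <- function(state, resident, mutant, params, moments,
                             tol = 1e-8, guard = TRUE) {
  d <- reconstruct_two(state, moments, tol, guard)
  r <- strain_rates(resident, params)
  m <- strain_rates(mutant, params)
  al <- params$alpha
  xS <- d[["x_S"]]
  phi  <- if (xS > 0) r$g * d[["x_I"]] + r$l * d[["p_SI"]] / xS else r$g * d[["x_I"]]
  phip <- if (xS > 0) m$g * d[["x_J"]] + m$l * d[["p_SJ"]] / xS else m$g * d[["x_J"]]
  c(x_I = r$g * xS * d[["x_I"]] + (r$l + r$psi) * d[["p_SI"]] - al * d[["x_I"]],
    p_SI = -(phi + phip + r$psi + al) * d[["p_SI"]] + phi * d[["p_SS"]] +
      al * (d[["p_II"]] + d[["p_IJ"]]),
    p_IO = phi * d[["p_SO"]] - al * d[["p_IO"]],
    x_J = m$g * xS * d[["x_J"]] + (m$l + m$psi) * d[["p_SJ"]] - al * d[["x_J"]],
    p_SJ = -(phi + phip + m$psi + al) * d[["p_SJ"]] + phip * d[["p_SS"]] +
      al * (d[["p_JJ"]] + d[["p_IJ"]]),
    p_IJ = phi * d[["p_SJ"]] + phip * d[["p_SI"]] - 2 * al * d[["p_IJ"]],
    p_JJ = 2 * ((phip + m$psi) * d[["p_SJ"]] - al * d[["p_JJ"]]))
}

#' Integrate the pair dynamics
#'
#' Adaptive integration (deSolve, lsoda) of either the single-strain system
#' (3 state variables) or the resident + mutant system (7 state variables,
#' when `mutant` is supplied). The returned trajectory carries every
#' reconstructed density and the residuals of the two conservation
#' identities p_SS + 2 p_SI (+ 2 p_SJ + 2 p_IJ + p_JJ) + p_II = p_CC and
#' p_SO + p_IO (+ p_JO) = x_C - p_CC at every output time.
#'
#' @param state0 initial state ([pair_state()] / [two_strain_state()] or
#'   numeric vector of matching length).
#' @param times output time points (numeric vector).
#' @param strain resident [virus_strain()] (or bare G).
#' @param params an [epidemic_params()].
#' @param moments a [spatial_moments()].
#' @param mutant optional mutant strain; switches to the two-strain system.
#' @param rtol,atol integrator tolerances.
#' @param negative_guard `"error"` (default) fails on densities below
#'   -1e-10; `"clip"` floors them at 0 with a single warning.
#' @return data.frame of class `pair_trajectory`: time, state variables,
#'   reconstructed densities and conservation residuals.
#' @export
integrate_pair_dynamics <- function(state0, times, strain, params, moments,
                                    mutant = NULL, rtol = 1e-10, atol = 1e-12,
                                    negative_guard = c("error", "clip")) {
  negative_guard <- match.arg(negative_guard)
  two <- !is.null(mutant)
  y0 <- if (two) as_state_vec2(state0) else as_state_vec(state0)
  rates <- strain_rates(strain, params)
  clipped <- FALSE
  fn <- function(t, y, parms) {
    neg <- y < 0
    if (any(neg)) {
      if (any(y < -1e-10) && negative_guard == "error")
        stop(sprintf("negative density (min %.3g) during integration", min(y)))
      clipped <<- clipped || any(y < -1e-10)
      y[neg] <- 0
    }
    d <- if (two) deriv_two_strain(y, strain, mutant, params, moments, tol = 1e-6)
         else deriv_single(y, rates, params, moments, tol = 1e-6)
    list(unname(d))
  }
  out <- deSolve::ode(y = y0, times = times, func = fn, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  traj <- as.data.frame(out)
  if (clipped)
    warning("negative densities beyond -1e-10 were clipped to 0 during integration")
  rec <- t(apply(traj[, -1, drop = FALSE], 1L, function(y) {
    if (two) reconstruct_two(y, moments, tol = 1e-6)
    else reconstruct_single(y, moments, tol = 1e-6)
  }))
  traj <- cbind(traj["time"], as.data.frame(rec))
  if (two) {
    traj$resid_CC <- abs(traj$p_SS + 2 * traj$p_SI + 2 * traj$p_SJ +
      traj$p_II + 2 * traj$p_IJ + traj$p_JJ - moments$p_CC)
    traj$resid_CO <- abs(traj$p_SO + traj$p_IO + traj$p_JO -
      (moments$x_C - moments$p_CC))
  } else {
    traj$resid_CC <- abs(traj$p_SS + 2 * traj$p_SI + traj$p_II - moments$p_CC)
    traj$resid_CO <- abs(traj$p_SO + traj$p_IO - (moments$x_C - moments$p_CC))
  }
  class(traj) <- c("pair_trajectory", "data.frame")
  traj
}

#' Conservation residuals of an integrated trajectory
#'
#' Maximum absolute residual of the target-pair and target/non-target-pair
#' budgets along a trajectory from [integrate_pair_dynamics()].
#'
#' @param trajectory a `pair_trajectory`.
#' @export
conservation_residuals <- function(trajectory) {
  stopifnot(inherits(trajectory, "pair_trajectory"))
  c(CC = max(trajectory$resid_CC), CO = max(trajectory$resid_CO))
}
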