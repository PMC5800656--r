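#' Basic reproduction number (closed form)
#'
#' R0 = (g x_C + l q_C/C + sqrt((g x_C + l q_C/C)^2 + 4 g psi p_CC)) / (2 alpha),
#' the larger root of alpha^2 R^2 - alpha (g x_C + l q_C/C) R - g psi p_CC = 0.
#' In the extremes it reduces to the single-type quantities
#' rho_1 = beta_G x_C / alpha (completely global, G = 1: mass action among
#' target cells) and rho_0 = beta_L (1 - theta) q_C/C / alpha (completely
#' local, G = 0: the dyad heuristic of pair reproduction), exposed as
#' attributes `rho1` and `rho0`.
#'
#' @param strain a [virus_strain()] (or bare G value).
#' @param params an [epidemic_params()]; `alpha` must be positive.
#' @param moments a [spatial_moments()] with x_C > 0.
#' @return R0 (numeric scalar) with attributes `rho1` and `rho0`.
#' @export
basic_reproduction_number <- function(strain, params, moments) {
  if (params$alpha <= 0) stop("alpha must be positive for R0")
  if (moments$x_C <= 0) stop("q_C/C undefined: x_C must be positive")
  r <- strain_rates(strain, params)
  q <- moments$q_C_given_C
  A <- r$g * moments$x_C + r$l * q
  r0 <- (A + sqrt(A^2 + 4 * r$g * r$psi * moments$p_CC)) / (2 * params$alpha)
  attr(r0, "rho1") <- params$beta_G * moments$x_C / params$alpha
  attr(r0, "rho0") <- params$beta_L * (1 - params$theta) * q / params$alpha
  r0
}

#' Basic reproduction number via a numerical next-generation matrix
#'
#' Independent numerical route to R0: the implemented single-strain
#' derivative is linearized at the disease-free equilibrium
#' (x_I = p_SI = p_IO = 0, so p_SS = p_CC and p_SO = x_C - p_CC) by central
#' finite differences; the transmission components are read off the Jacobian
#' (g x_C from the susceptible-depletion entry, beta_L L(G) from the
#' pair-transmission entry, l q_C/C from the SI self-entry) and assembled
#' into the next-generation matrix over the two ways a cell can have been
#' infected -- globally (virion from anywhere, hence placed on a random
#' target cell with q_C/C target neighbors, all four of them available) or
#' locally (placed next to its infector, leaving the 1 - theta outside share):
#' K = (1/alpha) \[ g x_C, g x_C; (l + psi) q_C/C, l q_C/C \].
#' R0 is the spectral radius of K, computed by `eigen()`. The closed form is
#' never consulted.
#'
#' @inheritParams basic_reproduction_number
#' @export
r0_via_ngm <- function(strain, params, moments) {
  al <- params$alpha
  if (al <= 0) stop("alpha must be positive: transition matrix is singular")
  if (moments$x_C <= 0) stop("q_C/C undefined: x_C must be positive")
  rates <- strain_rates(strain, params)
  dfe <- c(x_I = 0, p_SI = 0, p_IO = 0)
  J <- pracma::jacobian(function(y) {
    unname(deriv_single(y, rates, params, moments, guard = FALSE))
  }, dfe)
  q <- moments$q_C_given_C
  gxC <- J[1, 1] + al          # global transmission onto all target cells
  bL_L <- J[1, 2] - 0          # l + psi = beta_L * L(G)
  lq_minus_psi <- J[2, 2] + 2 * al
  l <- (lq_minus_psi + bL_L) / (1 + q)
  Fmat <- rbind(c(gxC, gxC),
                c(bL_L * q, l * q))
  V <- diag(al, 2L)
  K <- Fmat %*% solve(V)
  ev <- eigen(K, only.values = TRUE)$values
  max(c(Re(ev[abs(Im(ev)) < 1e-12]), 0))
}

#' Endemic threshold test
#'
#' Evaluates the disease-free-equilibrium stability condition
#' alpha^2 - alpha (g x_C + l q_C/C) - g psi p_CC < 0 (endemic when
#' negative). When both rho_1 G and rho_0 L(G) are positive the equivalent
#' product form (1 - 1/(rho_1 G)) (1 - 1/(rho_0 L(G))) < 1/(1 - theta) is
#' evaluated as well, and agreement between the two forms and with R0 > 1 is
#' asserted.
#'
#' @inheritParams basic_reproduction_number
#' @return list with `endemic` (logical), `margin` (the quadratic
#'   left-hand side; negative inside the endemic region), `r0`, and
#'   `rho_form` (logical or NA when undefined).
#' @export
is_endemic <- function(strain, params, moments) {
  strain <- as_strain(strain)
  r <- strain_rates(strain, params)
  al <- params$alpha
  q <- moments$q_C_given_C
  margin <- al^2 - al * (r$g * moments$x_C + r$l * q) -
    r$g * r$psi * moments$p_CC
  endemic <- margin < 0
  r0 <- basic_reproduction_number(strain, params, moments)
  u <- attr(r0, "rho1") * strain$G
  v <- attr(r0, "rho0") * local_weight(strain$G, strain$tradeoff_exponent)
  rho_form <- if (u > 0 && v > 0)
    (1 - 1 / u) * (1 - 1 / v) < 1 / (1 - params$theta)
  else NA
  if (!is.na(rho_form) && rho_form != endemic && abs(margin) > 1e-10)
    stop("internal inconsistency: quadratic and rho-form endemic conditions disagree")
  if ((as.numeric(r0) > 1) != endemic && abs(margin) > 1e-10)
    stop("internal inconsistency: endemic condition disagrees with R0 > 1")
  list(endemic = endemic, margin = margin, r0 = as.numeric(r0),
       rho_form = rho_form)
}

# Feasible seeded state for steady-state searches: a small infected density
# with pairs at proportional mixing, the SI pair mass capped at half the
# target-target budget so p_II stays positive.
seed_state <- function(moments, frac = 0.01) {
  x_I <- frac * moments$x_C
  x_S <- moments$x_C - x_I
  q <- moments$q_C_given_C
  p_IO <- (1 - q) * x_I
  p_SI <- min(2 * q * x_S * x_I / moments$x_C, 0.5 * (x_I - p_IO))
  pair_state(x_I, p_SI, p_IO)
}

#' Endemic equilibrium of a single strain
#'
#' Integrates the single-strain pair dynamics from a small seeded infection
#' to a steady state (chunked adaptive integration until the largest
#' derivative component falls below `deriv_tol`, then Newton polishing on
#' the algebraic system to machine precision). If the endemic-threshold test
#' fails, the disease-free state is returned with `extinct = TRUE`.
#'
#' @inheritParams basic_reproduction_number
#' @param deriv_tol steady-state criterion on max |d state / dt|.
#' @param t_max total integration time budget before a non-convergence
#'   error is raised.
#' @param init_frac seeded infected fraction of x_C (default 0.01).
#' @return list of class `pair_equilibrium`: `state` (named vector
#'   x_I, p_SI, p_IO), `extinct`, `max_deriv`, `t_used`.
#' @export
endemic_equilibrium <- function(strain, params, moments, deriv_tol = 1e-9,
                                t_max = 1e4, init_frac = 0.01) {
  strain <- as_strain(strain)
  rates <- strain_rates(strain, params)
  if (!is_endemic(strain, params, moments)$endemic) {
    return(structure(list(state = c(x_I = 0, p_SI = 0, p_IO = 0),
                          extinct = TRUE, max_deriv = 0, t_used = 0),
                     class = "pair_equilibrium"))
  }
  y <- as_state_vec(seed_state(moments, init_frac))
  dfun <- function(z) deriv_single(z, rates, params, moments, tol = 1e-6)
  dfun_raw <- function(z) unname(deriv_single(z, rates, params, moments,
                                              guard = FALSE))
  t_used <- 0
  chunk <- 50
  repeat {
    traj <- integrate_pair_dynamics(y, c(0, chunk), strain, params, moments)
    y <- unlist(traj[nrow(traj), c("x_I", "p_SI", "p_IO")])
    t_used <- t_used + chunk
    if (max(abs(dfun(y))) < deriv_tol) break
    if (t_used >= t_max)
      stop(sprintf("no steady state within t_max = %g (max |deriv| = %.3g)",
                   t_max, max(abs(dfun(y)))))
  }
  # Newton polish: the integrated point is deep in the basin, a few steps
  # reach machine precision.
  for (i in 1:10) {
    d <- dfun(y)
    if (max(abs(d)) < 1e-13) break
    J <- pracma::jacobian(dfun_raw, y)
    step <- tryCatch(solve(J, unname(d)), error = function(e) NULL)
    if (is.null(step)) break
    y <- y - setNames(step, names(y))
  }
  structure(list(state = y, extinct = FALSE, max_deriv = max(abs(dfun(y))),
                 t_used = t_used),
            class = "pair_equilibrium")
}

#' Closed-form equilibrium of the completely global strain
#'
#' For G = 1 (no local infection) the endemic equilibrium has the closed
#' form x_I = x_C - alpha/beta_G,
#' p_SI = (1 - alpha/(beta_G x_C)) (alpha/(beta_G x_C)) p_CC,
#' p_IO = (1 - alpha/(beta_G x_C)) (x_C - p_CC): infection is independent of
#' neighborhood, so pairs factorize over the conditional structure. Below
#' the threshold beta_G x_C <= alpha the strain is extinct and the
#' disease-free state is returned.
#'
#' @param params an [epidemic_params()].
#' @param moments a [spatial_moments()].
#' @return a `pair_equilibrium` (see [endemic_equilibrium()]).
#' @export
global_strain_equilibrium <- function(params, moments) {
  a_rel <- params$alpha / (params$beta_G * moments$x_C)
  if (a_rel >= 1) {
    return(structure(list(state = c(x_I = 0, p_SI = 0, p_IO = 0),
                          extinct = TRUE, max_deriv = 0, t_used = 0),
                     class = "pair_equilibrium"))
  }
  st <- c(x_I = moments$x_C - params$alpha / params$beta_G,
          p_SI = (1 - a_rel) * a_rel * moments$p_CC,
          p_IO = (1 - a_rel) * (moments$x_C - moments$p_CC))
  structure(list(state = st, extinct = FALSE, max_deriv = 0, t_used = 0),
            class = "pair_equilibrium")
}
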