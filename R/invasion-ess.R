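#' Invasion growth rate of a rare mutant
#'
#' Linearizes the mutant block (x_J, p_SJ, p_IJ, p_JJ) of the two-strain
#' dynamics in the mutant variables at the resident's endemic equilibrium
#' (resident quantities frozen at their equilibrium values; the mutant force
#' of infection phi' = g' x_J + l' p_SJ / x_S is linear in the mutant
#' variables) and returns the dominant eigenvalue of the resulting 4 x 4
#' Jacobian. Self-invasion (mutant trait equal to the resident's) has growth
#' rate exactly zero: the susceptible-depletion entry g' x_S - alpha
#' vanishes at the resident equilibrium only as part of the full spectrum,
#' and neutrality is enforced by the structure of the equations, not by
#' special-casing.
#'
#' @param resident,mutant [virus_strain()] objects (or bare G values; the
#'   resident's trade-off exponent is applied to a bare mutant G).
#' @param params an [epidemic_params()].
#' @param moments a [spatial_moments()].
#' @param resident_eq optional precomputed `pair_equilibrium` for the
#'   resident (e.g. cached across a PIP row); computed if missing.
#' @return the dominant eigenvalue (numeric scalar).
#' @export
invasion_growth_rate <- function(resident, mutant, params, moments,
                                 resident_eq = NULL) {
  resident <- as_strain(resident)
  mutant <- as_strain(mutant, resident$tradeoff_exponent)
  if (is.null(resident_eq))
    resident_eq <- endemic_equilibrium(resident, params, moments)
  if (resident_eq$extinct)
    stop("resident is not endemic: test mutant establishment with basic_reproduction_number() instead")
  M <- mutant_jacobian(resident, mutant, params, moments, resident_eq)
  max(Re(eigen(M, only.values = TRUE)$values))
}

# Analytic Jacobian of the mutant block at the resident equilibrium; the
# finite-difference route through deriv_two_strain is kept as a test oracle.
mutant_jacobian <- function(resident, mutant, params, moments, resident_eq) {
  r <- strain_rates(resident, params)
  m <- strain_rates(mutant, params)
  al <- params$alpha
  y <- resident_eq$state
  d <- reconstruct_single(y, moments, tol = 1e-6)
  xS <- d[["x_S"]]
  phi <- r$g * d[["x_I"]] + if (xS > 0) r$l * d[["p_SI"]] / xS else 0
  rbind(
    c(m$g * xS - al,                        m$l + m$psi,                      0,       0),
    c(m$g * d[["p_SS"]],  -(phi + m$psi + al) + m$l * d[["p_SS"]] / xS,      al,      al),
    c(m$g * d[["p_SI"]],            phi + m$l * d[["p_SI"]] / xS,      -2 * al,       0),
    c(0,                                     2 * m$psi,                       0, -2 * al))
}

#' Can a rare mutant invade the resident?
#'
#' Thresholds the invasion growth rate at a neutrality tolerance: growth
#' rates within `eps_neutral` of zero (including the exactly-neutral
#' self-invasion) count as "cannot invade".
#'
#' @inheritParams invasion_growth_rate
#' @param eps_neutral neutrality tolerance (default 1e-8).
#' @export
can_invade <- function(resident, mutant, params, moments,
                       resident_eq = NULL, eps_neutral = 1e-8) {
  invasion_growth_rate(resident, mutant, params, moments, resident_eq) >
    eps_neutral
}

#' Pairwise invasibility plot over a strain grid
#'
#' Computes, for every ordered pair of grid strains, whether a rare mutant
#' can invade the resident at its endemic equilibrium. Residents that are
#' not endemic get `NA` rows. Resident equilibria are solved once per grid
#' strain; the 4 x 4 eigenvalue problem is then evaluated for all mutants.
#' Singular strategies are located where the direction of selection by
#' adjacent mutants changes and classified from the local invasion pattern:
#' an `ESS` is a strain neither neighbor can invade; a `repeller` is a
#' convergence-unstable point (selection points away on both sides); a
#' convergence-stable point whose neighbors do invade is reported as
#' `attractor`.
#'
#' @param grid a [strain_grid()].
#' @param params an [epidemic_params()].
#' @param moments a [spatial_moments()].
#' @param tradeoff_exponent trade-off exponent applied to every grid strain.
#' @param eps_neutral neutrality tolerance.
#' @return object of class `pip`: list with `G`, `invade` (logical matrix,
#'   rows = residents, cols = mutants, NA rows for non-endemic residents),
#'   `endemic` (logical vector), `singular` (data.frame G, type) and the
#'   inputs used.
#' @export
build_pip <- function(grid, params, moments, tradeoff_exponent = 1,
                      eps_neutral = 1e-8) {
  stopifnot(inherits(grid, "strain_grid"))
  G <- grid$G
  n <- length(G)
  strains <- lapply(G, virus_strain, tradeoff_exponent = tradeoff_exponent)
  eqs <- lapply(strains, function(s) {
    eq <- endemic_equilibrium(s, params, moments)
    if (eq$extinct) NULL else eq
  })
  endemic <- !vapply(eqs, is.null, logical(1))
  if (!any(endemic)) stop("no grid strain is endemic under these parameters")
  invade <- matrix(NA, n, n, dimnames = list(resident = NULL, mutant = NULL))
  for (i in seq_len(n)) {
    if (!endemic[i]) next
    lam <- vapply(strains, function(mut) {
      invasion_growth_rate(strains[[i]], mut, params, moments, eqs[[i]])
    }, numeric(1))
    invade[i, ] <- lam > eps_neutral
    invade[i, i] <- FALSE
  }
  singular <- classify_singular(G, invade, endemic)
  structure(list(G = G, invade = invade, endemic = endemic,
                 singular = singular, params = params, moments = moments,
                 tradeoff_exponent = tradeoff_exponent,
                 eps_neutral = eps_neutral),
            class = "pip")
}

# Direction of selection at each endemic grid strain from its adjacent
# mutants: +1 if only the upper neighbor invades, -1 if only the lower,
# 0 if neither (local ESS), 2 if both invade (the strain sits at an
# invadable singular point), NA if non-endemic.
selection_direction <- function(G, invade, endemic) {
  n <- length(G)
  dir <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!endemic[i]) next
    up <- if (i < n) isTRUE(invade[i, i + 1]) else FALSE
    down <- if (i > 1) isTRUE(invade[i, i - 1]) else FALSE
    dir[i] <- if (up && down) 2 else if (up) 1 else if (down) -1 else 0
  }
  dir
}

# ESS: a strain no adjacent mutant invades. Between-point singular
# strategies are located where the direction of selection flips, bridging
# any run of doubly-invadable points: -1 ... +1 is a repeller (selection
# points away on both sides), +1 ... -1 an attractor.
classify_singular <- function(G, invade, endemic) {
  n <- length(G)
  dir <- selection_direction(G, invade, endemic)
  out <- data.frame(G = numeric(0), type = character(0))
  for (i in seq_len(n)) {
    if (is.na(dir[i]) || dir[i] != 0) next
    interior <- i > 1 && i < n
    out <- rbind(out, data.frame(
      G = G[i], type = if (interior) "ESS" else "boundary ESS"))
  }
  signed <- which(!is.na(dir) & dir != 2 & dir != 0)
  for (k in seq_len(length(signed) - 1)) {
    i <- signed[k]; j <- signed[k + 1]
    if (any(is.na(dir[i:j])) || any(dir[i:j] == 0)) next
    if (dir[i] == -1 && dir[j] == 1)
      out <- rbind(out, data.frame(G = (G[i] + G[j]) / 2, type = "repeller"))
    if (dir[i] == 1 && dir[j] == -1)
      out <- rbind(out, data.frame(G = (G[i] + G[j]) / 2, type = "attractor"))
  }
  out[order(out$G), , drop = FALSE]
}

#' @export
print.pip <- function(x, ...) {
  cat(sprintf("<pairwise invasibility plot> %d strains, %d endemic\n",
              length(x$G), sum(x$endemic)))
  if (nrow(x$singular) == 0) cat("  no singular strategies located\n")
  else {
    for (i in seq_len(nrow(x$singular)))
      cat(sprintf("  singular strategy at G = %.3f (%s)\n",
                  x$singular$G[i], x$singular$type[i]))
  }
  invisible(x)
}

#' Local ESS strains on a grid
#'
#' A grid strain is a local ESS when it is endemic and neither adjacent grid
#' strain can invade it (one-sided at the endpoints). Returns the G values;
#' an empty result carries a `diagnosis` attribute.
#'
#' @inheritParams build_pip
#' @param pip optional precomputed [build_pip()] result (grid/params ignored
#'   if supplied).
#' @export
find_local_ess <- function(grid, params, moments, tradeoff_exponent = 1,
                           eps_neutral = 1e-8, pip = NULL) {
  if (is.null(pip))
    pip <- build_pip(grid, params, moments, tradeoff_exponent, eps_neutral)
  G <- pip$G
  n <- length(G)
  ess <- logical(n)
  for (i in seq_len(n)) {
    if (!pip$endemic[i]) next
    up <- if (i < n) isTRUE(pip$invade[i, i + 1]) else FALSE
    down <- if (i > 1) isTRUE(pip$invade[i, i - 1]) else FALSE
    ess[i] <- !up && !down
  }
  out <- G[ess]
  if (length(out) == 0) {
    attr(out, "diagnosis") <- if (!any(pip$endemic))
      "no endemic strain on the grid" else "every endemic strain is invadable by a neighbor"
  }
  out
}

#' Closed-form invasion condition against the completely global strain
#'
#' A rare mutant with proportion of global infection G' < 1 invades the
#' G = 1 resident at its endemic equilibrium if and only if
#' beta_G / (beta_L (1 - theta + G' theta)) < p_CC / x_C^2
#' (linear trade-off). The left side decreases to beta_G / beta_L as
#' G' -> 1, so the completely global strain resists *all* mutants exactly
#' when the clustering index stays below beta_G / beta_L; with equal rates
#' the threshold is complete spatial randomness.
#'
#' @param mutant_G mutant trait value G' in \[0, 1).
#' @param params an [epidemic_params()].
#' @param moments a [spatial_moments()].
#' @export
invades_global_strain <- function(mutant_G, params, moments) {
  if (params$beta_G * moments$x_C <= params$alpha)
    stop("G = 1 resident is not endemic (beta_G * x_C <= alpha)")
  lhs <- params$beta_G /
    (params$beta_L * (1 - params$theta + mutant_G * params$theta))
  lhs < moments$clustering
}

#' Grid strain maximizing R0
#'
#' Argmax of the closed-form basic reproduction number over a strain grid;
#' used to contrast the evolutionarily stable proportion of global infection
#' with naive R0 maximization (under strong clustering the ESS sits well
#' below the R0 maximizer because of self-shading).
#'
#' @inheritParams build_pip
#' @return the maximizing G with attribute `r0` (the maximum).
#' @export
r0_maximizing_G <- function(grid, params, moments, tradeoff_exponent = 1) {
  r0s <- vapply(grid$G, function(g) {
    as.numeric(basic_reproduction_number(
      virus_strain(g, tradeoff_exponent), params, moments))
  }, numeric(1))
  out <- grid$G[which.max(r0s)]
  attr(out, "r0") <- max(r0s)
  out
}

#' Clustering threshold at which the completely global strain becomes invadable
#'
#' Scans p_CC upward on a regular grid at fixed x_C, solving the G = 1
#' resident equilibrium numerically and testing every grid mutant's invasion
#' growth rate; returns the clustering index p_CC / x_C^2 of the first p_CC
#' at which some mutant's growth rate exceeds the neutrality tolerance.
#'
#' @param params an [epidemic_params()].
#' @param x_C target-cell density.
#' @param p_CC_range range of pair densities to scan, `c(lo, hi)`.
#' @param p_CC_step scan step (default 0.005).
#' @param grid a [strain_grid()] of candidate mutants (default 101 strains).
#' @param eps_neutral neutrality tolerance.
#' @return clustering threshold (numeric) with attributes `p_CC` (the pair
#'   density at which invasion first occurs) and `scan` (data.frame of
#'   p_CC, clustering, invadable).
#' @export
scan_global_ess_threshold <- function(params, x_C, p_CC_range,
                                      p_CC_step = 0.005,
                                      grid = strain_grid(),
                                      eps_neutral = 1e-8) {
  p_CC_vals <- seq(p_CC_range[1], p_CC_range[2], by = p_CC_step)
  mutants <- grid$G[grid$G < 1]
  invadable <- logical(length(p_CC_vals))
  for (k in seq_along(p_CC_vals)) {
    mom <- spatial_moments(x_C, p_CC_vals[k])
    eq <- endemic_equilibrium(virus_strain(1), params, mom)
    lam <- vapply(mutants, function(gp) {
      invasion_growth_rate(virus_strain(1), virus_strain(gp), params, mom, eq)
    }, numeric(1))
    invadable[k] <- any(lam > eps_neutral)
  }
  first <- which(invadable)[1]
  if (is.na(first))
    stop("no scanned p_CC renders the completely global strain invadable")
  out <- p_CC_vals[first] / x_C^2
  attr(out, "p_CC") <- p_CC_vals[first]
  attr(out, "scan") <- data.frame(p_CC = p_CC_vals,
                                  clustering = p_CC_vals / x_C^2,
                                  invadable = invadable)
  out
}
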