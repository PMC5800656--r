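#' Epidemic rate parameters
#'
#' Transmission and recovery rates of the lattice SIS model. `beta_G` is the
#' rate constant of global (cell-free, mass-action) infection, `beta_L` the
#' rate constant of local (cell-to-cell) infection, `alpha` the rate at which
#' an infected cell reverts to susceptible (death with immediate replacement,
#' or recovery), and `theta` the inverse neighborhood size, 1/4 for the
#' 4-neighbor lattice, which splits local transmission pressure on the
#' susceptible member of an SI pair into a within-pair share (psi) and an
#' outside share (l).
#'
#' @param beta_G,beta_L,alpha non-negative rates (per unit time).
#' @param theta inverse neighborhood size in (0, 1\]; default 1/4.
#' @export
epidemic_params <- function(beta_G, beta_L, alpha, theta = 0.25) {
  stopifnot(beta_G >= 0, beta_L >= 0, alpha >= 0, theta > 0, theta <= 1)
  structure(list(beta_G = beta_G, beta_L = beta_L, alpha = alpha,
                 theta = theta), class = "epidemic_params")
}

#' Virus strain: proportion of global infection and trade-off shape
#'
#' A strain is characterized by the proportion of global infection
#' G in \[0, 1\] it commits to; the complementary weight on local infection is
#' L(G) = 1 - G^s, where `s` is the trade-off exponent (s = 1 is the linear
#' trade-off; s = 0.5 makes local capacity decay with the square root of G,
#' the nonlinear case that produces evolutionary bistability).
#'
#' @param G proportion of global infection in \[0, 1\].
#' @param tradeoff_exponent trade-off exponent s > 0 (default 1, linear).
#' @export
virus_strain <- function(G, tradeoff_exponent = 1) {
  stopifnot(is.numeric(G), length(G) == 1L, G >= 0, G <= 1,
            tradeoff_exponent > 0)
  structure(list(G = G, tradeoff_exponent = tradeoff_exponent),
            class = "virus_strain")
}

#' Local-infection weight of a strain
#'
#' L(G) = 1 - G^s; L(0) = 1, L(1) = 0 and L is non-increasing in G.
#'
#' @param G proportion(s) of global infection.
#' @param tradeoff_exponent trade-off exponent s.
#' @export
local_weight <- function(G, tradeoff_exponent = 1) 1 - G^tradeoff_exponent

#' Effective transmission rates of a strain
#'
#' Maps a strain and the epidemic parameters onto the three rate constants of
#' the pair dynamics: the global rate g = beta_G * G, the outside-pair local
#' rate l = beta_L * L(G) * (1 - theta), and the within-pair local rate
#' psi = beta_L * L(G) * theta, so that l / psi = (1 - theta) / theta.
#'
#' @param strain a [virus_strain()] (or a bare G value, linear trade-off).
#' @param params an [epidemic_params()].
#' @return list with components `g`, `l`, `psi`.
#' @export
strain_rates <- function(strain, params) {
  strain <- as_strain(strain)
  L <- local_weight(strain$G, strain$tradeoff_exponent)
  list(g = params$beta_G * strain$G,
       l = params$beta_L * L * (1 - params$theta),
       psi = params$beta_L * L * params$theta)
}

as_strain <- function(x, tradeoff_exponent = 1) {
  if (inherits(x, "virus_strain")) x
  else virus_strain(x, tradeoff_exponent)
}

#' Evenly spaced strain grid on \[G_min, G_max\]
#'
#' The trait space used in the invasibility analysis and in the evolutionary
#' simulation: `n_strains` equally spaced G values with both endpoints
#' included (default 101 strains on \[0, 1\], i.e. a step of 0.01).
#'
#' @param n_strains number of strains (default 101).
#' @param G_min,G_max trait range endpoints.
#' @export
strain_grid <- function(n_strains = 101L, G_min = 0, G_max = 1) {
  stopifnot(n_strains >= 2L, G_min < G_max, G_min >= 0, G_max <= 1)
  structure(list(G = seq(G_min, G_max, length.out = n_strains),
                 n_strains = as.integer(n_strains)),
            class = "strain_grid")
}
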