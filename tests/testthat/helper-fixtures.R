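# Shared parameter sets. The headline configuration: equal global and local
# rate constants, moderate recovery, half the lattice covered by target
# cells with mild aggregation.
fig_params <- function(alpha = 1, beta_G = 10, beta_L = 10)
  epidemic_params(beta_G, beta_L, alpha)

headline_moments <- function(p_CC = 0.3, x_C = 0.5) spatial_moments(x_C, p_CC)

# Random admissible parameter draw: positive rates, defined moments.
draw_params <- function(endemic_margin = NULL) {
  repeat {
    p <- epidemic_params(runif(1, 0.5, 20), runif(1, 0.5, 20),
                         runif(1, 0.2, 8))
    x_C <- runif(1, 0.15, 0.95)
    mom <- spatial_moments(x_C, runif(1, 0.05 * x_C, x_C))
    G <- runif(1)
    if (is.null(endemic_margin)) return(list(params = p, moments = mom, G = G))
    if (is_endemic(virus_strain(G), p, mom)$margin < -endemic_margin)
      return(list(params = p, moments = mom, G = G))
  }
}

# Brute-force ordered target-target adjacency count (independent oracle for
# the vectorized shift-based counter).
brute_p_CC <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  cnt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    nbs <- rbind(c(r %% nr + 1L, c), c((r - 2L) %% nr + 1L, c),
                 c(r, c %% nc + 1L), c(r, (c - 2L) %% nc + 1L))
    for (k in 1:4) if (mask[nbs[k, 1], nbs[k, 2]]) cnt <- cnt + 1L
  }
  cnt / (4 * nr * nc)
}

# Feasible seeded state for integration tests (mirrors the package's
# internal steady-state seed).
seed_state_for_test <- function(moments) pairsis:::seed_state(moments)
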