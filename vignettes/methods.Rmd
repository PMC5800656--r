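---
title: "Methods: pair-approximation SIS dynamics and the evolution of global versus local infection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pair-approximation SIS dynamics and the evolution of global versus local infection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological setting and the model

Within a host, a virus can transmit by releasing free virions into the
extracellular medium (global, cell-free infection: any susceptible target
cell can be hit) or by passing directly into an adjacent cell through
membrane fusion or a virological synapse (local, cell-to-cell infection).
The two routes trade off: retaining and polarizing virions at the cell
surface makes local transfer efficient but withholds them from the free
pool. `pairsis` models the within-host evolution of the proportion of
global infection on a two-dimensional lattice in which each site
permanently carries either a target cell (for this virus) or a non-target
cell. Target cells cycle susceptible → infected → susceptible (SIS): death
with immediate replacement and plain recovery are equivalent at this level
of description. Persistent infections (the motivating case) give the virus
enough time for mutation-limited trait substitution, which is what the
adaptive-dynamics layer assumes.

Space enters through exactly two summary statistics of the target-cell
arrangement: the density $x_C$ and the ordered neighbor-pair density
$p_{CC}$ (fraction of the $4N$ ordered (site, neighbor) pairs with both
members target cells, periodic wrap). Their ratio $q_{C/C} = p_{CC}/x_C$ is
the conditional probability that a target cell's neighbor is again a target
cell, and $p_{CC}/x_C^2$ is the clustering index: 1 at complete spatial
randomness (CSR), above 1 for aggregated arrangements, below 1 for
over-dispersed ones. A central empirical property of the model — probed by
the Monte-Carlo layer on deterministic stripe, checkerboard and gasket
patterns versus moment-matched random lattices — is that these two moments
capture essentially everything the evolutionary outcome depends on.

## Strains, rates and the trade-off

A strain commits a proportion $G \in [0,1]$ to global infection and retains
local weight $L(G) = 1 - G^s$. The default $s = 1$ is the linear trade-off;
$s = 0.5$ (local capacity decaying with the square root of $G$) is the
built-in nonlinear case and produces evolutionary bistability. The exponent
is a single parameter rather than two hard-coded cases so both regimes run
through one code path (`virus_strain(G, tradeoff_exponent)`).

With global and local rate constants $\beta_G, \beta_L$ and inverse
neighborhood size $\theta = 1/4$, the working rates are
$g = \beta_G G$, $l = \beta_L L(G)(1-\theta)$ and
$\psi = \beta_L L(G)\theta$: a susceptible cell in a susceptible–infected
pair is infected by its pair partner at rate $\psi$ and from everything
else at the force of infection $\varphi = g x_I + l\, p_{SI}/x_S$.

## Pair approximation

The dynamics track singlet and ordered pair densities and close triples at
the pair level ($q_{\sigma/\sigma'\sigma''} \approx q_{\sigma/\sigma'}$).
Three variables are independent for one strain —
$(x_I, p_{SI}, p_{IO})$ — because total density, $x_C$ and $p_{CC}$ are
conserved; everything else is reconstructed:
$x_S = x_C - x_I$, $p_{II} = x_I - p_{SI} - p_{IO}$,
$p_{SS} = p_{CC} - 2p_{SI} - p_{II}$, $p_{SO} = (x_C - p_{CC}) - p_{IO}$.
The reconstruction makes the two pair budgets identities, and the test
suite verifies their residuals stay below $10^{-8}$ along every integrated
trajectory — this guards the plumbing (integrator, reconstruction,
state handling), not a delicate numerical balance.

For a resident plus a rare mutant there are seven independent variables
$(x_I, p_{SI}, p_{IO}, x_J, p_{SJ}, p_{IJ}, p_{JJ})$. One structural choice
deserves note: the resident's SI equation carries a loss term
$-\varphi' p_{SI}$ (the susceptible member of a resident SI pair being
captured by a mutant, which converts the pair to IJ), mirroring the
$+\varphi' p_{SI}$ gain in the IJ equation. Without this term the
bookkeeping is inconsistent: relabelling half of a resident population as
an identical "mutant" would change aggregate trajectories by order
$10^{-3}$. With it the neutral reduction is exact to integrator precision
($\sim 10^{-13}$), which the suite asserts by integrating a 50/50 split of
a transient against the single-strain system. The ordered-pair convention
matters here: a random $\varepsilon$-labelling sends $p_{II} \mapsto$
$(1-\varepsilon)^2 p_{II}$ with $p_{IJ} = \varepsilon(1-\varepsilon)p_{II}$
(ordered), so a 50/50 split has $p_{IJ} = p_{JJ} = p_{II}/4$.

## R0 by two independent routes

The closed form
$$R_0 = \frac{g x_C + l q_{C/C} + \sqrt{(g x_C + l q_{C/C})^2 + 4 g \psi p_{CC}}}{2\alpha}$$
is the larger root of
$\alpha^2 R^2 - \alpha(g x_C + l q_{C/C})R - g\psi p_{CC} = 0$. It reduces
to $\rho_1 = \beta_G x_C/\alpha$ for a purely global strain (mass action
among target cells) and $\rho_0 = \beta_L(1-\theta)q_{C/C}/\alpha$ for a
purely local one (a pair of infected cells must beget more than one pair).

`r0_via_ngm()` recomputes $R_0$ without the closed form: it linearizes the
implemented derivative at the disease-free equilibrium by central finite
differences, reads the transmission components off the Jacobian, assembles
the next-generation matrix over the two *types* of newly infected cell —
globally infected (virion lands on a random target cell, all four neighbor
slots available, each target with probability $q_{C/C}$) and locally
infected (placed beside its infector, leaving the $1-\theta$ outside
share) —
$$K = \frac{1}{\alpha}\begin{pmatrix} g x_C & g x_C \\ (l+\psi)q_{C/C} & l\, q_{C/C}\end{pmatrix},$$
and returns the spectral radius by `eigen()`. The trace and determinant of
$K$ reproduce the quadratic above, so the two routes agree to machine
precision; the suite checks $10^{-8}$ agreement on 100 random parameter
draws, and that the endemic-threshold quadratic, its product
($\rho$) form and $R_0 > 1$ all classify identically.

## Endemic equilibria

`endemic_equilibrium()` integrates from a seeded infection until the
largest derivative component falls below $10^{-9}$ (chunks of 50 time
units, budget $t_{\max} = 10^4$), then Newton-polishes the algebraic
steady-state system to $\sim 10^{-13}$. The polish matters: invasion
eigenvalues inherit the equilibrium error, and the neutrality identity
$\lambda(G, G) = 0$ is required at $10^{-8}$.

The seed places $x_I = 0.01 x_C$ with pairs at proportional mixing; the SI
pair mass is capped at half the infected pair budget so $p_{II}$ stays
positive ($p_{SI,0} = \min(2 q_{C/C} x_S x_I / x_C,\; 0.5(x_I - p_{IO,0}))$,
$p_{IO,0} = (1 - q_{C/C}) x_I$). Equilibria are seed-insensitive (asserted
by test at seed fractions 0.01 and 0.4). For the completely global strain
the closed form
$\hat x_I = x_C - \alpha/\beta_G$,
$\hat p_{SI} = (1-a)a\,p_{CC}$,
$\hat p_{IO} = (1-a)(x_C - p_{CC})$ with $a = \alpha/(\beta_G x_C)$
is available exactly and doubles as an oracle for the integration + polish
pipeline (componentwise agreement at $10^{-6}$ over random draws, typically
far better).

## Invasion fitness, PIPs and the ESS

Invasion fitness is the dominant eigenvalue of the $4\times4$ Jacobian of
the mutant block $(x_J, p_{SJ}, p_{IJ}, p_{JJ})$, linearized in the mutant
variables at the resident equilibrium; the matrix is assembled analytically
(the finite-difference Jacobian of the full two-strain derivative is the
test oracle for it). Self-invasion is neutral to machine precision without
special-casing — a structural property the suite verifies across the
grid. The trait space is 101 equally spaced strains on $[0,1]$; a strain is
a **local ESS** when neither adjacent grid strain can invade it (growth
rates within $10^{-8}$ of zero count as "cannot invade"). `build_pip()`
solves each resident equilibrium once and reuses it across all mutants.

Singular strategies are read off the direction of selection by adjacent
mutants: points no neighbor invades are ESSs; where the direction flips
from down to up — possibly across a run of doubly-invadable grid points,
which is how a repeller manifests at finite grid resolution — a
**repeller** is reported, and the up-to-down flip an attractor. Under the
linear trade-off the model produces a unique singular strategy (interior
ESS, or a boundary ESS at $G = 1$ below the clustering threshold); under
$s = 0.5$ at strong clustering the PIP shows bistability: both extremes
protected, separated by a repeller near $G \approx 0.4$.

For the completely global resident the invasion condition has a closed
form. Written as implemented,
$$\frac{\beta_G}{\beta_L\,(1-\theta+G'\theta)} < \frac{p_{CC}}{x_C^2}.$$
The grouping of the trade-off factor is the one consistent with the
condition's own corollaries — the left side decreases to $\beta_G/\beta_L$
as $G' \to 1$, so complete protection holds exactly when clustering stays
below $\beta_G/\beta_L$, and at equal rates the threshold is CSR — and it
is verified exhaustively in the tests against the numerical eigenvalue
route: sign agreement for every mutant on the grid across random parameter
draws spanning $\beta_G \lessgtr \beta_L$. A plausible alternative grouping
(factor in the numerator) fails that comparison decisively and is not
implemented. The condition applies to the linear trade-off; for other
exponents the numerical route is authoritative.

## Spatial structure generators

CSR lattices draw sites independently. Prescribed-moment lattices fix the
target count to $\mathrm{round}(x_C N)$ up front (so $x_C$ is exact and
conserved) and then greedily swap a random target site with a random
non-target site whenever the swap strictly reduces
$|p_{CC} - \text{target}|$, ties rejected — a deterministic-acceptance
Metropolis refinement. No temperature is used: the objective is a single
scalar and greedy improvement reaches any feasible $p_{CC}$ in
$[\max(0, 2x_C - 1), x_C]$ in practice within $\sim 10^4$–$10^5$ proposals
on a $100 \times 100$ lattice (tolerance $10^{-3}$, proposal budget
$10^6$); non-convergence raises an error carrying the best-achieved value.
An acceptance rule flag (`mh_rule`) records that strict improvement is the
implemented policy.

Deterministic patterns (width-1 stripes, $5\times5$ checkerboard) have
exact moments $(0.5, 0.25)$ and $(0.5, 0.4)$ on $100\times100$. The
Sierpinski gasket is rasterized by the bitwise rule
$\mathrm{AND}(r, c) = 0$; since gasket rasterizations differ, its moments
are *measured and reported*, never asserted (this raster gives
$x_C = 0.1845$, $p_{CC} = 0.093$ at $100 \times 100$).

## The Monte-Carlo simulator

The stochastic layer runs the same process site by site: synchronous
fixed-step updates in which a susceptible target cell is infected with
probability $1 - e^{-h\,\Delta t}$, where
$h = \sum_k [\beta_G G_k x_{I_k} + \beta_L L_k n_k/4]$ sums the global
pressure of every strain (density over the whole lattice) and the local
pressure of the site's four neighbors; the infecting strain is drawn
proportionally to its hazard contribution; an infected cell recovers with
probability $1 - e^{-\alpha \Delta t}$. All events in a step use the state
at the start of the step, so a run is a deterministic function of
configuration and seed (asserted by test). On each transmission the strain
mutates with probability $\mu$ to an adjacent grid strain, half each side,
bouncing off the grid ends.

Defaults, chosen once as a realistic operating point and not revisited:
step $\Delta t = 0.05$, automatically reduced so that no per-site event
probability exceeds 0.1 per step (a hazard bound from full local pressure
plus global pressure at the lattice's target density; an oversized explicit
$\Delta t$ is an error, not silently accepted); initial infection 10% of
target cells, uniformly at random, all carrying one designated strain
(mean trait 0.5 for evolution runs unless stated); mutation probability
$\mu = 0.01$ per transmission. The qualitative claims checked against the
simulator (trait ordering across clustering levels, survival thresholds)
are deliberately insensitive to these knobs.

What the simulator emulates: finite-population, spatially explicit
transmission with frozen habitat heterogeneity, demographic stochasticity
and mutation-limited trait motion. What it does not: within-cell kinetics,
superinfection and its exclusion mechanisms, immune pressure, cell
movement, three-dimensional tissue. Consequently, agreement between the
simulator and the pair approximation shows the closure is adequate for
these lattices — not that either describes any particular tissue. Known
systematic differences, visible in the outputs: the mean trait under
mutation–selection balance stays off the extremes (the population is
polymorphic), and strongly local strains do worse in simulation than the
pair approximation predicts, because large infected clusters violate the
pair closure and finite clusters limit the available hosts.

## Problem sizes and numerical choices

The test suite runs the analytical layer at full size (101-strain grids,
$100\times100$ lattices) and scales the stochastic layer to what the
properties need: $50\times50$ lattices for the quantitative
pair-approximation comparisons (mean infected density within three
Monte-Carlo standard errors of $\hat x_I$; trait ordering over 5000 time
units at $\mu = 0.01$), smaller lattices and horizons for behavioral unit
tests. Integrator tolerances are `rtol = 1e-10`, `atol = 1e-12` (lsoda);
densities below $-10^{-10}$ during integration are an error by default
(`negative_guard = "clip"` floors them with a warning); reconstructed
densities may undershoot zero by at most the stated tolerance and are
floored. Degenerate inputs are first-class: saturated lattices are refused
by the CSR and Metropolis generators but constructible explicitly; an
all-non-target lattice reports its conditional moments as undefined rather
than NaN; $\alpha = 0$ is a valid dynamical regime but an error where a
lifetime $1/\alpha$ is required ($R_0$).

## Limitations

The pair approximation is least reliable exactly where local infection
dominates; the adaptive-dynamics layer assumes separation between
epidemiological and evolutionary timescales and rare mutants, both of
which the mutation-limited simulator only approximates; and the
evolutionary analysis is within-host only — between-host transmission
imposes selection pressures this package does not model.
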