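---
title: "Model and methods behind syntromix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind syntromix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(syntromix)
```

## The system being modelled

`syntromix` simulates a two-species surface-attached microbial community in
which resources are traded for a service. Species A (the *producer*)
consumes a shared limiting nutrient R supplied from the liquid bulk above
the biofilm and excretes a metabolic by-product E that is toxic to itself.
Species B (the *cross-feeder*) can consume E, so its presence both feeds it
and detoxifies the producer's microenvironment — food for detoxification.
Depending on how toxic E is to A and how strongly B depends on E, the net
interaction between the species ranges from competition through
exploitation to mutualism, and the emergent spatial arrangement of the two
lineages ranges from segregated towers to finely intermixed branches.

The simulation is an individual-based model: discrete cells with continuous
positions grow by local Monod kinetics, divide at a threshold size, and
resolve crowding by mechanically shoving one another; dissolved solutes
live on a regular grid and are driven to quasi-steady state by a
reaction–diffusion solver every biological timestep, because molecular
diffusion is orders of magnitude faster than cellular growth.

## Growth kinetics

All species use one growth law with an obligacy weight
$\omega \in [0, 1]$:

$$\mu = (1-\omega)\,\mu_{max,R}\,\frac{R}{K_R+R}\,\frac{1}{1+E/K_{tox}}
      \;+\; \omega\,\mu_{max,E}\,\frac{E}{K_E+E}.$$

* The producer has $\omega = 0$, finite $K_{tox}$, and excretes
  $\gamma_E$ grams of E per gram of new biomass.
* The cross-feeder variants differ only in $\omega$:
  `B_ncf` (0), `B_facW` (0.25), `B_facI` (0.5), `B_facS` (0.75),
  `B_obl` (1, and $\mu_{max,R}=0$: it cannot grow without its partner).
* Inhibition is *simple* (non-competitive): the factor $1/(1+E/K_{tox})$
  multiplies the producer's nutrient reaction. The toxicity axis of the
  scenario grid sweeps $K_{tox}$ over
  $\{\infty, 5, 1, 0.2, 0.04\}$ g/L (level 1 = non-toxic, level 5 =
  highly toxic).

Uptake follows the yields: $q_R = \mu_R/Y_R$, $q_E = \mu_E/Y_E$, and
production is $\gamma_E\,\mu$ for producers.

## Calibration of the stoichiometric defaults

No complete kinetic table is published for this model family, so the
defaults here are package choices. Most are generic
(all $\mu_{max} = 1\,h^{-1}$, $K_{R,A} = 0.05 < K_{R,B} = 0.25$ g/L,
$K_E = 0.05$ g/L: the producer is the better nutrient competitor). The
yields were pinned by one analytic argument rather than by trial: at a
stable coexistence the by-product budget in the active layer closes,
$\gamma_E \mu X_A \approx \mu X_B / Y_E$, so the producer's equilibrium
share of the community is approximately

$$f_A \;=\; \frac{1}{1+\gamma_E Y_E},$$

biased slightly upward by diffusive loss of E to the bulk. A reported
coexistence point of roughly one third producers therefore requires
$\gamma_E Y_E \approx 2$. Keeping the mass-balance rule
$\gamma_E = (1-Y_{R,A})/Y_{R,A}$ (substrate not fixed as biomass leaves as
by-product) and $Y_E = 0.5$, this gives $Y_{R,A} = 0.2$,
$\gamma_E = 4$, and $Y_{R,B} = 0.14$ to preserve the producer's
efficiency advantage. This was fixed before any simulation was run and is
not revisited; the acceptance suite then measures the emergent coexistence
frequency from the full spatial model.

## Solute fields and the quasi-steady solver

Fields live on a uniform 2D grid (default 260 × 200 µm at 4 µm; a vertical
cross-section of the biofilm). Boundary conditions: the bulk value is
imposed on every voxel above the biofilm front plus a 40 µm boundary layer
(Dirichlet at the face, second order); the substratum is a zero-flux wall;
lateral boundaries are cyclic by default, with zero-flux and
bulk-permeable variants used by the lineage-tracking scenarios.

Each timestep solves $D\nabla^2 S + r(S) = 0$ per field. The reaction term
is relinearised around the current iterate as $r(S) \approx p - kS$ with
$k \ge 0$, using the *tangent* of the Monod terms (Newton-like) — the
linearisation is exact at the evaluation point, so convergence is judged
on true nonlinear residuals (relative tolerance $10^{-6}$, at most 200
iterations, an error on exhaustion). The producer's self-limiting
production ($\partial p_E/\partial E < 0$) is folded into the diagonal so
the linear operator stays an M-matrix and concentrations stay
non-negative. Fields are swept Gauss–Seidel style; full Picard steps are
taken while the residual shrinks and a 0.7 damping factor engages only if
it grows. The 5-point Laplacian is assembled per active region and solved
by sparse Cholesky with a cached symbolic analysis. Diagnostics attached
to every solve report residuals and the boundary-influx versus
net-consumption budget, which the test suite checks for closure.

## Cells

A cell is a disc of fixed biomass density (200 g/L) and out-of-plane depth
equal to the grid spacing. Mass grows as $m \leftarrow m e^{\mu \Delta t}$
with $\mu$ evaluated at the containing voxel; at a radius of 2 µm the cell
divides with a uniform split fraction in [0.45, 0.55], daughters placed at
a random angle touching each other. Crowding is resolved by iterative
pairwise shoving (half the overlap each, along the centre line; fully
superposed pairs separate along +x for determinism), with a spatial hash
for neighbour search. Shoving moves biomass but never creates or destroys
it. Seeded cells draw their initial mass from the stationary size
distribution of a binary-fission population (number density $\propto
1/m^2$ on $[m_{div}/2, m_{div})$), which makes a freshly seeded,
unconstrained population track the well-mixed exponential
$N(t) = N_0 e^{\mu t}$ — one of the cross-checks in the acceptance suite.

One caveat of pairwise Gauss–Seidel shoving: the worst-pair overlap can
rise transiently in the first sweeps of a badly packed configuration
before relaxing; the tests therefore assert eventual, not per-sweep,
monotone decrease.

## Scenarios

`build_scenario()` catalogues the experiments: the toxicity × obligacy
grid on random lawns (60 cells per species in coculture, 60 total in
monoculture — an additive design), the space-only variant (each species
gets a private nutrient field, removing nutrient competition but not space
competition), a control pair of identical species differing only in color,
two-microcolony inocula (30 µm bands separated by 70 µm edge-to-edge, a
package decision where the geometry was ambiguous) with an
initial-segregation dial, a by-product diffusion sweep (multipliers 10,
1.4, 1, 0.14), the near/far lineage-tagging setup (clonal colonies, halves
tagged by whether they face the partner colony, non-cyclic boundaries
permeable to E, 120 h), and a bidirectional cross-feeding variant.

Inoculation details that were genuinely open were fixed as: uniform
placement within the colony band at $y = r$ followed by a single
relaxation pass (with an enlarged sweep budget, since mounding a dense
band is a one-off); row order is shuffled before relaxing so the
deterministic sweep order cannot stratify the mound by species; colony-1
receives the fraction $(1+s)/2$ of species 1 (rounded, complement to
colony 2) so totals are conserved exactly at every dial setting.

## Analysis statistics

* **Segregation index.** For each cell, the fraction of neighbours within
  10 µm (5 µm variant available) sharing its species; cells with no
  neighbours are excluded. Species means $seg_X$ are normalised against
  the global frequency, $s_X = (seg_X - \bar p_X)/(1 - \bar p_X)$ — the
  relatedness-style normalisation, pinned by its endpoints: 1 for clonal
  colonies, 0 in expectation under random labelling, negative when
  over-mixed; validated against those endpoints and against a brute-force
  all-pairs oracle in the tests.
* **Growth rate** is count-based: $(N_f - N_i)/(t_f - t_i)$.
* **Interaction classification** uses log relative growth
  $\log(X_{co}/X_{mono})$ per species (for the obligate cross-feeder,
  $\log(X_{co})$, since it has no monoculture baseline): both positive =
  mutualism, both negative = competition, mixed = exploitation named for
  the beneficiary. A band of $\pm 0.02$ on the log scale guards the
  all-neutral knife edge; if only one effect falls inside the band the raw
  signs decide, which preserves mirror symmetry under species exchange.
* **Productivity gain**: $(A_{co}+B_{co})-(A_{mono}+B_{mono})$.
* **Near/far advantage**: per species, growth rate of the colony half
  seeded facing the partner minus the outward half.
* **Replicate density correlation**: Pearson correlation of final producer
  versus cross-feeder counts across replicate seeds.

## What the synthetic world does and does not establish

All inputs are generated: there is no external data. The generator
reproduces the stated experimental design (inoculum sizes, colony
geometry, boundary modes, diffusion multipliers, durations) at desk scale:
a 260 × 200 µm domain at 4 µm resolution, hundreds-to-thousands of cells,
and a 0.05 h default timestep (heavy acceptance runs use 0.1 h, which
still respects the $\mu\,\Delta t \le 0.1$ rule; the suite checks that
halving the timestep moves community size by < 2%). Relative to
full-scale biofilm simulations this compresses absolute population sizes
and the dynamic range of the segregation index — qualitative contrasts (toxicity trends,
classification shifts, diffusion effects) are reproduced as trends across
scenario contrasts, not as absolute values. Green qualitative tests
therefore establish directional agreement at reduced scale, under fixed
seeds declared in the tests; they do not establish quantitative agreement
with any full-scale reference values, which are not available to target.

Replicate-correlation signatures (the demographic-feedback diagnostic)
proved the most scale-sensitive statistic. Because the statistic is defined
*after lineage contact*, and the two colonies only touch around 110 h at
this domain size, the sign test is evaluated at 168 h. Under strong
interdependence the expected positive correlation then emerges clearly
(+0.6). Under weak interdependence the expected *negative* correlation does
not reproduce at desk scale: between-replicate variance is dominated by
fluctuations shared by both lineages (total supply usage, mound geometry),
while the competitive seesaw acts only at the narrow contact interface, so
the measured correlation stays mildly positive. The corresponding test
expectation is deliberately left failing rather than weakened; it marks a
known scale limitation, not a defect of the statistic.

## Numerical choices and degenerate inputs

Tolerances: solver $10^{-6}$ relative residual; shoving stops at 5%
pairwise overlap (50 sweeps cap per step, warning on exhaustion);
concentrations are clipped at zero with the clip magnitude reported in the
solve diagnostics. Division below threshold, negative concentrations,
non-finite rates, empty snapshots, zero-variance correlations, and
unknown scenario or boundary names raise typed errors rather than
propagating silently. Runs stop early with a flag when the biofilm front
reaches 80% of the domain height. Trajectories are bitwise reproducible
for a fixed (scenario, seed): all randomness flows through R's RNG, and
the C++ mechanics are deterministic, including the +x tie-break for
coincident cells.

## Known limitations

2D cross-section only; no motility, chemotaxis, detachment, EPS, or
regulatory switching of resource use; no death by default (an optional
maintenance rate is provided but off); quasi-steady solutes (no advection
or transient transport); single biofilm per domain. With no absolute
parameter table available to match, quantitative agreement is only claimed
for the one population-level anchor the acceptance suite targets (the
coexistence frequency) and the segregation-index endpoints.
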