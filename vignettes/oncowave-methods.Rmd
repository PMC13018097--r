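---
title: "Models and numerical methods in oncowave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in oncowave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oncowave)
```

`oncowave` studies one biological scenario — an oncolytic virus spreading
through a growing tumour — at four levels of description that share a single
parameter set. This vignette explains the models, their assumptions, the
numerical choices, and what the test suite does and does not establish.

## The model hierarchy

**State variables.** `u` — uninfected tumour cell density; `i` — infected
cell density; `v` — free virion concentration; pressure is identified with
total cell density, `rho = u + i` (the simplest closure; more elaborate
pressure laws are out of scope). Units: densities in cells/mm (1D) or
cells/mm² (2D), time in hours, space in mm.

**Cell processes.** Uninfected cells divide or die logistically at rate
`G(rho) = p (1 - rho/K)` (division where `G > 0`, death where `G < 0`),
become infected at rate `beta * v / K`, and move. Infected cells move but do
not divide; they lyse at rate `q`, each lysis releasing `alpha` virions.
Virions diffuse with `D_v` and are cleared at rate `q_v`; uptake of virions
by cells is neglected.

**Movement rules.** *Undirected*: ordinary diffusion `D_U`. *Pressure-driven*:
cells hop only toward lower total density, giving the cross-diffusion flux
`-(D_P/K) u grad(rho)` in the continuum. The defaults satisfy
`D_P = 8 D_U`, which makes the untreated front speeds of the two rules equal
(`2 sqrt(D_U p) = sqrt(D_P p / 2)`), so treatment effects can be compared at
matched invasion speed.

**The four continuum systems** solved by `pde_solve()` are every combination
of {undirected `U`, pressure-driven `P`} x {explicit virus `3`, quasi-steady
virus `2`}. The quasi-steady reduction assumes viral turnover is much faster
than cell turnover, `v ~ (alpha q / q_v) i`, collapsing infection into the
cell-to-cell rate `beta_tilde = beta alpha q / q_v`. The non-spatial
versions of the `3`- and `2`-variable systems are handled by the `ode_*`
functions.

**The hybrid lattice model** (`abm_simulate()`) is the stochastic original
of which the PDEs are the large-number limit: integer counts per site, all
event probabilities proportional to `tau` and evaluated on the time-`n`
state, with the viral field updated by a deterministic-in-form balance
equation forced by the binomial lysis counts. The movement probability is
`theta = 2 tau D / delta^2` (1D) or `4 tau D / delta^2` (2D).

## Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| `p` | max duplication rate | 1.87e-2 | 1/h |
| `q` | lysis rate of infected cells | 4.17e-2 | 1/h |
| `q_v` | viral clearance | 0.167 or 1.00 | 1/h |
| `alpha` | burst size | 580 or 3500 | virions/cell |
| `beta` | infection rate | 7.00e-4 | virions/(cells h) |
| `D_U` | undirected cell diffusivity | 1.88e-4 | mm²/h |
| `D_P` | pressure-driven coefficient | 1.504e-3 (= 8 `D_U`) | mm²/h |
| `D_v` | viral diffusivity | 1.00e-2 | mm²/h |
| `K` | carrying capacity | 1e3 (1D) / 1e4 (2D) | cells/mm, cells/mm² |
| `R_u`, `R_v`, `R_i` | initial plateau radii | 2.6 / 0.5 / 0 | mm |
| `V_0` | initial viral plateau | 2.67e4 (1D) / (2.67e3)² (2D) | virions/mm^d |
| `tau`, `delta` | lattice steps | 0.02 h, 0.1 mm | |

The two `(alpha, q_v)` pairs keep `alpha/q_v` approximately constant, hence
nearly the same `beta_tilde ~ 0.10` 1/h (0.1014 vs 0.1022 — the pairs are
*not* exactly ratio-matched), isolating the purely dynamical role of viral
turnover speed. `K` is dimension-dependent; `model_params()` never rescales
a user-supplied `K`, it only warns when it differs from the reference value
for the chosen dimension.

Initial conditions are radial plateaux: `u0 = 0.9 K` inside `R_u`, no
infected cells, virus `V_0` inside `R_v` (`R_v = R_u` models a wide
injection). A radius of zero (the default `R_i`) means the species is
absent; an infinite radius fills the whole domain (used for
established-tumour studies, `u(0, .) = K`).

## Numerical schemes

**PDEs.** Explicit Euler in time (`dt = 1e-3` h), `dx = 0.1` mm. Linear
diffusion uses the centred 3-point stencil; the radial Laplacian closes the
`r = 0` singularity by symmetry (`4 (f_1 - f_0)/dx^2`, the L'Hopital form).
The cross-diffusion flux is first-order donor-cell upwinding on shared face
velocities `V_{j+1/2} = -(D_P/K)(rho_{j+1} - rho_j)/dx`; both species use
the same face velocity because both ride the same pressure gradient. In
radial mode the conservative `1/r d/dr (r . )` form is used with zero face
flux at the origin. Boundaries are no-flux. Negative undershoots are clipped
to zero and counted; anything beyond `-1e-12` triggers a warning because
donor-cell upwinding under CFL should be positivity-preserving. The linear
CFL number at defaults is `dt D_v/dx^2 = 1e-4`.

First-order upwinding adds numerical diffusion: the pressure-driven tumour
front at `dx = 0.1` runs a few percent fast (the refinement test in
`test-pde.R` quantifies the drift, which halves as the grid is refined), so
pressure-front speed assertions carry a 15% band where linear-diffusion
fronts get 5%.

**Lattice model.** Implemented in C++ (via Rcpp) with R's own RNG, so
`set.seed()` makes runs bitwise reproducible. Within a step: lysis, then
infection, then demography, then movement, then the viral update — all
probabilities from the time-`n` state, so the order only matters at
`O(tau^2)`; this order also makes the lysis count at a site well-defined at
the pre-movement position, where the virions are released. Multinomial
movement is sampled as sequential conditional binomials. Daughter cells are
placed at the parent's site and may move in the step they are born
(indistinguishable from moving first and dividing after, at `O(tau^2)`).
Every event probability is checked at runtime and the simulation aborts if
any leaves `[0, 1]`.

**ODEs.** A self-contained adaptive Dormand–Prince RK5(4) integrator
(`rtol = 1e-9` for cycle work): no ODE-solver package is assumed, the
systems are small and non-stiff at the parameter ranges used, and limit
cycle amplitude extraction near the Hopf point is tolerance-sensitive —
the suite checks the attractor envelope is stable under a 100-fold
tolerance tightening.

**Wave speeds.** The explicit-virus invasion speed is computed by linear
determinacy: linearise about the uninfected background `(u0, 0, 0)`; for a
profile `exp(-lambda x)` the `(i, v)` subsystem grows at the largest
eigenvalue `mu(lambda)` of a 2x2 matrix, and the selected speed is
`c* = min_{lambda > 0} mu(lambda)/lambda`, minimised on `log lambda` over
`[1e-2, 1e3]` 1/mm with Brent's method at `1e-10` relative tolerance
(equivalent to the prescribed golden-section: same bracket, same unimodal
objective, tighter iterate). Two non-obvious facts the tests pin down:
at `D_v = D_U` the relation collapses exactly to `c* = 2 sqrt(D_U nu)` with
`nu` the reaction-matrix growth rate — which is strictly below the
quasi-steady speed at finite `q_v`; and measured front speeds approach `c*`
slowly (Bramson-type transients), so empirical fits use late windows and
domains large enough that the front never feels the boundary.

**Quasi-steady comparison.** `quasi_steady_check()` compares an
explicit-virus solution with its reduction on the same grid. The reduced
model carries no virus, so the viral initial condition is translated into
its quasi-steady infected equivalent `i0 + (q_v/(alpha q)) v0`; without
this, the standard initial data (`i0 = 0`) could never start an infection
in the reduced system. Both reference parameter pairs translate `V_0` into
the same `i0 ~ 184` cells/mm. For convergence studies in the `q_v -> Inf`
limit, initial data should instead be placed on the slave manifold
(`v0 = alpha q i0 / q_v`), as the monotone-limit test does — a free viral
pulse carries a `q_v`-dependent infective dose that otherwise masks the
convergence.

## Outcome statistics

The tumour control probability over a seeded lattice ensemble is the
fraction of replicates whose uninfected population is extinct by time `t`
(absorbing: nothing regrows from zero cells). The infection control
probability is evaluated pointwise in time by default because infected cells
can re-emerge while virus persists; an absorbing variant is available. The
Poissonian counterparts from radial continuum solutions,
`exp(-2 pi int_0^R u(t, r) r dr)`, use the computational radius for `R`
(densities vanish beyond the front) and the solver's per-step trapezoid
integrals. Maxima over time exclude `t = 0` because the standard initial
condition has no infected cells, so `ICP(0) = 1` is an artefact of the
starting state, not an outcome.

## The stochastic-extinction experiment

The high-efficacy preset (2D, `alpha = 3500`, `q_v = 8.33e-2` — half the
lower reference clearance — wide injection `R_v = R_u`) drives a binary
outcome: in most replicates every cell is infected during the first
oscillation trough and the tumour dies within the first ~200 h; in a few,
a handful of cells escape infection and regrow. The acceptance suite runs
24 replicates per movement rule at the reference resolution to 500 h and
checks the survival fractions against the reference values 8% (undirected)
and 19% (pressure-driven) within binomial 95% bands, the 200 h extinction
window, and eradication of the infection.

Two scaling notes, decided before the assertions were frozen. Horizon:
500 h suffices because extinctions close by 200 h and the infection clears
by ~400–500 h (1500 h in the full-scale experiment adds nothing but cost to
these statistics). Resolution: a half-resolution lattice (`delta = 0.2`,
`tau = 0.08`) was evaluated and rejected — it inflates the pressure-driven
survival fraction roughly 2.5-fold, because coarser sites smooth the local
viral field and change escape statistics; the full-resolution ensembles run
in ~2 min each.

## What the synthetic world does and does not establish

All inputs are synthetic: plateaux initial conditions and the reference
parameter table. A green suite establishes internal consistency of the
hierarchy — lattice means against ODE right-hand sides, lattice profiles
against PDE solutions, PDE fronts against dispersion relations, discrete
against Poissonian control probabilities — at the reference parameters. It
does not establish anything about real tumours: parameters come from
heterogeneous literature sources, the pressure law is the simplest possible,
there is no immune response, no virion uptake, and 2D continuum runs assume
radial symmetry (the lattice model is fully 2D and is exactly where the
non-radial stochastic phenomenology — patchy extinction, finger-like
infection fronts — appears).

## Known limitations

* First-order upwinding smears sharp pressure fronts at `dx = 0.1`; halve
  the grid (as the supplementary-scale studies require) when front *shape*
  matters.
* `hopf_scan()` measures cycle envelopes by integration past a transient;
  very close to the Hopf point the convergence to the limit cycle is slow
  (critical slowing down) and the reported amplitudes are lower bounds.
* The pressure-driven invasion speed under active treatment has no closed
  form here; `untreated_front_speed(params, effective_density = )` exposes
  the density-scaled variant as an explicitly experimental formula, and
  empirical `track_front()` measurement is the supported route.
* Eigenvalue classification reports `"marginal"` within `1e-10` of the
  imaginary axis rather than guessing a side.
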