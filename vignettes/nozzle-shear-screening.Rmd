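---
title: "Shear-stress screening of extrusion bioprinting nozzles: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shear-stress screening of extrusion bioprinting nozzles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(nozzleflow)
```

## The problem

In extrusion bioprinting a cell-laden hydrogel is pushed through a thin print
nozzle, and the shear stress the ink experiences in the nozzle is one of the
main suspects for the low post-printing cell viability of the technique.
Stress cannot be measured in situ, but for a given nozzle geometry, ink
rheology and drive condition it can be computed. `nozzleflow` implements that
computation at three levels of fidelity and wraps it in a screening pipeline:
a constrained Latin-hypercube design over the commercially available nozzle
geometries, batch flow solves, and a Gaussian-process sensitivity analysis of
the maximum shear stress (MSS), plus a packaged literature compilation
linking computed MSS to measured cell viability.

## Models

### Rheology

Bioinks are modelled as incompressible generalized-Newtonian power-law
(Ostwald–de Waele) fluids,
$$\eta = K\dot\gamma^{\,n-1}, \qquad \tau = \eta\dot\gamma = K\dot\gamma^{\,n},$$
with consistency $K$ (Pa s$^n$) and flow index $n$ (shear-thinning for
$n<1$). Three reference inks ship with the package (`bioink_library()`):
strongly shear-thinning Pluronic F127 ($n=0.127$, $K=406$), alginate
($n=0.335$, $K=55.7$) and the nearly power-law-Newtonian alginate–gelatin
blend ($n=0.608$, $K=13.3$), all at density 1000 kg/m³, with their customary
printing pressures (200, 340, 80 kPa). Temperature dependence, thixotropy and
yield stress are out of scope, as is treating suspended cells as a second
phase (reasonable while cell diameter is small against the nozzle radius).

### Geometry

Two axisymmetric nozzle families are parameterized in mm: *blunted* (barrel
radius `r_big`, length `l_upper`, abruptly contracting into a tube of radius
`r_small` and length `l_lower`) and *conical* (piecewise-linear taper
`r_big` → `r_middle` over the upper section and `r_middle` → `r_small` over
the lower). The true wall contour of commercial nozzles between the barrel
and the lower section (fillets, shoulder angle) is not published; the
package uses the two simplest shapes consistent with the catalogue
parameters — a 90° shoulder for blunted, linear tapers for conical. Conical
geometries must satisfy `r_small < r_middle < r_big`; candidate designs
violating `r_big > r_middle` are invalid by construction.

### Closed-form tube solution

For a straight tube the fully developed power-law Poiseuille solution is
closed form ($\tau_w = \Delta p R/2L$, $V_{avg}$, $Q$, and the velocity
profile; `pipe_*()` functions). It ignores the barrel, entrance development
and inertia. It serves two roles: the oracle every numerical solver is
validated against, and the "analytical model" baseline that the literature
often uses for MSS estimates.

### Quasi-1D reduced solver

`solve_reduced()` integrates the local fully developed wall-shear pressure
gradient $2\tau_w(R(z))/R(z)$ along the nozzle (lubrication approximation)
and adds a kinetic-energy correction
$\alpha(n)\,\tfrac12\rho\,(V_{exit}^2-V_{inlet}^2)$. The correction matters:
at catalogue scales the exit velocity under constant pressure reaches tens of
m/s and the inertial share of the pressure budget reaches hundreds of kPa.
$\alpha(n)$ is the kinetic-energy flux factor of the fully developed profile
(closed form in `alpha_energy()`; $\alpha(1)=2$, $\alpha\to1$ for plug flow);
a `plug` option sets $\alpha=1$. The true factor lies in between because the
profile does not fully redevelop after the contraction. No empirical
contraction-loss coefficient is added: fitting one against reference CFD
values would be calibration, and the 2D solver captures that loss
mechanistically. Pressure-driven solves invert the strictly increasing
`pressure_required()` by bracketed bisection on $\log Q$ (relative tolerance
1e-8).

The reduced model's MSS is the largest *fully developed* wall value along
the nozzle. It deliberately excludes the stress concentration at the
re-entrant shoulder corner and at the exit lip, and is therefore a lower
bound on the 2D result — on matched cases the finite-volume MSS is never
below it. Under constant pressure this has a visible consequence: the
blunted MSS rises with `r_small` only while the flow is viscosity-limited
(up to roughly `r_small` ≈ 0.2 mm for alginate); beyond that the
kinetic-energy limit flattens and gently reverses the 1D trend, whereas
corner-resolved 2D values keep rising.

### Axisymmetric finite-volume solver

`solve_fvm()` solves steady laminar incompressible flow in the full nozzle
on a staggered (MAC) grid in $(r,z)$ with a SIMPLE pressure–velocity
coupling written in C++: first-order upwind convection, implicit
$\eta\nabla u$ diffusion with the axisymmetric curvature sink in the radial
momentum equation, radial-line TDMA momentum sweeps and ADI pressure
corrections. The viscosity is refreshed every outer iteration from the full
strain-rate second invariant at cell centres — shear *and* extensional
components — and the stress field $\tau=\eta\dot\gamma$ uses the same
invariant, because in a converging cone the extension along the axis and the
thin developing wall layer both contribute to the maximum stress.

Numerical choices that matter:

* **Regularization.** $\eta\to\infty$ as $\dot\gamma\to0$ for $n<1$; the
  shear rate is floored at $\dot\gamma_{min}=10^{-3}\,s^{-1}$. The barrel
  flows at shear rates near the floor, so the regularized viscosity contrast
  between barrel and exit tube spans about four orders of magnitude. MSS is
  insensitive to the floor (it lives at the highest shear rates); the floor
  mainly sets the (ill-conditioned) near-axis viscosity.
* **Initialization.** Each column starts from the fully developed power-law
  profile carrying the target flux. A plug start is a trap for strongly
  shear-thinning inks: the flattened core reads near-zero shear rate, gets
  the floored (huge) viscosity, and the Picard iteration then crawls toward
  a false plug for thousands of iterations.
* **Relaxation.** Under-relaxation is chosen by regime unless set
  explicitly: 0.5 (velocity) / 0.2 (pressure) for straight-through
  geometries, 0.3 / 0.1 when the barrel-to-exit contraction exceeds a factor
  two (where the regularized-viscosity contrast is largest), scaled down
  further when the generalized (Metzner–Reed) Reynolds number of the exit
  tube exceeds 50 and again above 300. Residual growth triggers an automatic
  in-iteration back-off, and outright divergence restarts the solve at half
  relaxation. Catalogue contraction flows at $Re\sim500$ develop a weak
  oscillatory jet instability at the shoulder that only converges under
  gentle relaxation; conversely, strongly shear-thinning straight-tube flows
  converge poorly when over-damped, which is why the regime split exists.
* **Wall representation.** The wall is a staircase mask on the structured
  grid (no body-fitted cells). The reference spacing, 0.005 mm radially and
  0.010 mm axially, is always applied across the exit region where the
  stress peaks; the barrel is coarsened geometrically. Corner and exit-lip
  stresses are mesh-limited quantities: they are reported *at the reference
  spacing*, and `grid_refinement_study()` documents their mesh dependence.
* **Boundary conditions.** No-slip walls, uniform plug inflow, fixed outlet
  pressure; the inlet profile choice is immaterial because the inlet is the
  wide barrel. A constant-pressure drive is imposed by matching the
  area-averaged inlet–outlet static pressure difference to the target via a
  warm-started secant iteration on the flow rate (relative tolerance 0.5%,
  i.e. the converged state satisfies the constant-Δp condition to that
  accuracy); this is far more robust at high Reynolds number than a direct
  pressure boundary in the inner iteration and yields the same converged
  state.

Straight-tube validation: at $dr=R/50$ the computed wall shear, velocity
profile and pressure gradient match the closed-form solution within 2% for
all four reference flow indices (0.127–1.0), measured at a fully developed
mid-tube station (a plug inlet needs a development length, and comparing a
developing region against a fully developed formula would conflate model and
discretization error).

## Design of experiments

`lhs_design()` draws a maximin Latin hypercube over the catalogue box
(`r_small` 0.05–0.42, `r_middle` 1–3.5, `r_big` 1.5–4.5, `l_lower` 4–20,
`l_upper` 3–15 mm): the best of 50 random Latin hypercubes under the
largest-minimal-distance criterion (the exact space-filling criterion used
in the original screening is not published; maximin over candidates is the
common default of the R `lhs` tool family). The conical constraint is
enforced by re-pairing the realized `r_big` values against `r_middle` with a
random greedy matching — permuting realized values leaves every
one-dimensional stratified projection untouched, unlike rejecting and
redrawing whole designs. A feasible matching always exists for the catalogue
ranges. Everything is deterministic given the seed.

Campaigns (`run_campaign()`) default to the reduced solver: 200 designs
solve in about two seconds, which makes the six campaigns (three inks × two
shapes) a desk-scale computation, and the screening conclusions — which
parameters drive MSS — are identical between solvers because the solvers
rank geometries the same way even though the reduced MSS level is a lower
bound. Finite-volume campaigns are supported for design subsets.

## Surrogate and sensitivity

`fit_gp()` fits a stationary anisotropic squared-exponential Gaussian
process to campaign responses, inputs scaled to $[-1,1]$ and response
standardized; hyperparameters (ARD length scales, signal variance, nugget)
maximize the marginal likelihood with weak log-normal priors (MAP), with
five optimizer restarts under a fixed seed. This replaces a Bayesian treed
GP used historically for this analysis: the campaign responses are smooth
in the geometry (held-out $R^2 > 0.9$), so a stationary GP supports the same
conclusions — effect shapes and relative sensitivities — at a fraction of
the machinery. We fit the log of MSS for campaign responses since MSS spans
a decade and is multiplicative in the geometry.

`main_effect()` integrates the other inputs out by Monte Carlo under
independent uniform inputs on the scaled box (common random numbers across
the grid; centred over the grid). `sobol_indices()` uses the Saltelli
pick-freeze scheme with the Jansen total-effect estimator on the GP
predictive mean, with a bootstrap over Monte-Carlo rows for the box-plot
spread; estimates are validated in the test suite against closed-form
variance decompositions (linear and Ishigami-type functions). The input
measure treats the conical box as a full box, ignoring the
`r_big > r_middle` truncation (the GP is fit to valid designs only); the
alternative — sensitivity under the truncated measure — would mix the
constraint geometry into the indices. `rank_parameters()` flags inputs with
total index below 0.05 as negligible; ties break by declaration order.

## Viability linkage

`builtin_studies()` ships the literature compilation of blunted-nozzle
printing experiments (power-law parameters, pressure or flow-rate ranges,
nozzle size, lower length, reported MSS and viability ranges, cell type) as
a digit-faithful CSV fixture. Two readings of its ambiguous nozzle-size
column ("diameter (Rs, mm)") are supported; the default treats it as a
diameter (exit radius = value/2), the reading under which the compilation's
own fully developed wall-stress values are reproduced by the solvers (e.g.
the myoblast/Schwann-cell row's low-flow endpoint computes to 0.41 kPa
against a printed 0.41). `simulate_records()` re-solves each study's
low/high drive endpoint through a blunted nozzle, filling the unreported
entrance radius and upper length from a catalogue default (3.5 mm / 4.0 mm);
a zero-pressure endpoint is the unsheared 2D control. The viability range is
paired monotonically (low drive ↔ high viability), which is the compilation's
own reading and is conservative for rank-based association.
`viability_association()` reports per-study Spearman correlations (≥3
points) or endpoint trends, and pooled correlations, separately for
stem-cell studies — the group with the most consistent adverse response to
shear. No cell-specific damage model is fitted; residence-time effects are
out of scope.

## Problem sizes and determinism

The test suite and the acceptance script run the finite-volume solver at the
reference spacing in the exit region (about 7,000–10,000 fluid cells for the
single-nozzle reference cases, with the barrel coarsened and, for the
conical stress case, the lower-section axial spacing graded from 0.010 mm at
the exit) and the reduced solver for the 200-design campaigns. These sizes
were chosen so the full chain — including the straight-tube oracle
comparisons at $dr = R/50$ — completes on a single CPU in minutes while
staying inside the stated tolerances; flow-rate and pressure quantities are
grid-converged far earlier than the corner stresses. All solvers are
deterministic; stochastic components (design generation, GP restarts, Monte
Carlo, bootstrap) take explicit seeds and record them in their outputs.

## What the synthetic campaigns do and do not show

The campaigns emulate the *screening conditions* of the study they
reproduce: idealized axisymmetric geometry, single-phase power-law rheology,
constant drive. Passing tests show the solver chain is internally consistent
and reproduces the published single-nozzle table within its tolerances where
the published values are themselves consistent with the governing equations.
They do not show anything about real printing phenomena excluded by the
model: cell-scale two-phase effects, viscoelasticity and die swell,
transient start-up, temperature gradients, or residence-time-dependent cell
damage. The viability linkage is correlational, across heterogeneous cell
types and protocols, and inherits every reporting gap of the underlying
experiments.

## Known limitations

* The staircase wall under-resolves oblique tapered walls between the
  refined exit region and the barrel; MSS on strongly tapered cones is
  biased low relative to body-fitted meshes at equal spacing. Corner/lip
  stresses are mesh-limited by nature and comparable only at a stated grid.
* SIMPLE with upwind convection is first-order accurate; flow-rate and
  pressure predictions converge quickly under refinement but carry a few
  percent discretization error at campaign resolutions.
* The reduced model's kinetic-energy correction uses a fully developed
  $\alpha(n)$; in short nozzles the effective factor is smaller, so the
  reduced pressure requirement errs high at high flow rates (conservative
  for printability estimates).
* The GP assumes stationarity; responses with regime changes inside the box
  (e.g. the near-Newtonian conical exit-radius response) are captured in
  shape but can smooth over sharp inflections.
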