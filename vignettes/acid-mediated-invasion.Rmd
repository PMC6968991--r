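---
title: "Cooperative acid-mediated tumour invasion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative acid-mediated tumour invasion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidinvasion)
```

## The model

Invading a tissue requires two distinct abilities: removing the stromal
cells that suppress tumour growth, and remodelling the extra-cellular
matrix (ECM) that blocks movement. `acidinvasion` simulates a
one-dimensional tissue slice in which these abilities are carried by two
*separate* tumour phenotypes, so that invasion — if it happens — is a
cooperative phenomenon:

* `S(x,t)` — stroma (healthy cells). Grows logistically and is killed by
  acid.
* `T_A(x,t)` — acid-producing (glycolytic, Warburg-type) tumour cells.
* `T_M(x,t)` — matrix-degrading tumour cells (via matrix-degrading
  enzymes).
* `L(x,t)` — lactic acid.
* `M(x,t)` — ECM density, a non-diffusing physical obstacle.

In dimensionless form (densities scaled by carrying capacities, time by the
stromal growth rate, space by the acid diffusion length) the system is

$$
\begin{aligned}
\partial_t S   &= S(1-S) - \delta S L,\\
\partial_t T_A &= \rho_T T_A (1 - c_S S - T_A - c_{M\!,A} T_M)
                 + \Delta_T \,\partial_x\!\left[(1-M)\,\partial_x T_A\right],\\
\partial_t T_M &= \rho_T T_M (1 - c_S S - c_{A\!,M} T_A - T_M)
                 + \Delta_T \,\partial_x\!\left[(1-M)\,\partial_x T_M\right],\\
\partial_t L   &= \rho_L (T_A - L) + \partial_x^2 L,\\
\partial_t M   &= -\kappa\, T_M M,
\end{aligned}
$$

on $x\in[0,1]$ with zero-flux boundaries. The two phenotypes are
biologically identical apart from their special abilities (equal growth
rates, capacities and motilities); they interact through Lotka–Volterra
competition, and both are obstructed by the matrix through the mobility
factor $1-M$ — movement ceases entirely where the matrix is intact
($M = 1$).

### Parameters

| group | meaning | default |
|---|---|---|
| $\delta$ | acid-induced stromal death strength | 12.5 |
| $\rho_T$ | tumour/stroma growth-rate ratio | 1 |
| $\Delta_T$ | tumour/acid diffusivity ratio | $4\times10^{-5}$ |
| $\rho_L$ | acid turnover rate | 70 |
| $\kappa$ | matrix degradation rate | 10 |
| $c_S$ | stromal competition on tumour | 1.5 |
| $c_{M,A}$, $c_{A,M}$ | inter-phenotype competition | swept on $[0,2]$ |

The defaults (see `dimensionless_params()`) are the reference
parameterisation of the acid-mediated-invasion literature, with the matrix
degradation rate adapted from enzyme-kinetics estimates. $c_S > 1$ encodes
that intact stroma excludes tumour cells; $\delta > 1$ that acid at tumour
capacity kills stroma. Both are assumptions of the stability analysis, so
the constructor warns (but does not refuse) when they are violated. One
dimensionless time unit corresponds to 11.57 days and one length unit to
2.24 cm (`unit_scales()`), so the default horizon $t=50$ is roughly 575
days.

The dimensional-to-dimensionless map (`nondimensionalise()`) is exercised
algebraically: the underlying dimensional values are not part of the
package's reference configuration, which is specified directly in
dimensionless form.

## Initial data and its placement

Initial interfaces are regularised steps (`regularised_step()`): compactly
supported, $C^1$, equal to 1 on the plateau and 0 beyond the transition of
width $\omega$. The builder (`initial_state()`) seeds

* tumour fields and acid at density 1 on $[0,\sigma_{tumour}]$
  (default $\sigma_{tumour} = 0.1$),
* stroma and matrix absent there and intact beyond
  $\sigma_{tissue} + \omega$ (defaults $\sigma_{tissue} = 0.2$,
  $\omega = 0.1$).

A placement decision is buried here: we interpret $\sigma$ as the distance
the tumour has already infiltrated, i.e. the end of the full-density
plateau, with the smooth transition occupying $[\sigma, \sigma+\omega]$
*ahead* of it. The alternative reading (transition ending at $\sigma$)
would leave the "infiltrated" tumour at full density nowhere and would move
the intact-matrix wall from $x=0.3$ to $x=0.2$. The plateau reading is the
one consistent with the single-population stall positions the package
reproduces (below); since all profiles shift together, competition-sweep
comparisons are unaffected by this choice up to a translation.

## Numerical scheme

Space is discretised on an equi-spaced grid (default 200 points,
$h \approx 5\times10^{-3}$) with the variable-diffusion central stencil

$$
\partial_x (D\,\partial_x u)\big|_r \approx \tfrac{1}{2h^2}\left[
 (D_{r-1}+D_r)u_{r-1} - (D_{r-1}+2D_r+D_{r+1})u_r + (D_r+D_{r+1})u_{r+1}
\right],
$$

with $D = 1-M$ for the tumour fields and $D = 1$ for acid; for constant $D$
it reduces to the three-point Laplacian. Zero-flux boundaries are realised
by ghost-point reflection of both $u$ and $D$, which keeps the discrete
operator conservative under trapezoidal summation (asserted by the tests).
The resulting ODE system is integrated by a variable-order implicit
multistep (BDF) method via `deSolve::ode(method = "bdf")` with an
internally generated banded Jacobian — the state is interleaved per grid
point, so the bandwidth is at most 8. Default tolerances are $10^{-10}$
(relative and absolute). The production right-hand side is compiled C; a
line-by-line pure-R twin (`assemble_rhs()`) is kept as the readable
reference, and the test suite holds the two equal.

### Stabilisation: negativity guard and extinction floor

Two guards make the stiff integration robust, both configurable through
`solver_settings()`:

1. **Negativity guard.** A linear restoring term $-\lambda u$ (default
   $\lambda = 100$) is added wherever a field has gone (slightly) negative.
   A restoring term is preferred over hard clipping because it preserves
   the smoothness the implicit integrator relies on.
2. **Extinction floor.** The logistic source of each cell field is gated
   off (through a $C^1$ ramp) where that field lies below a floor of
   $10^{-6}$. This deals with what ecologists call *atto-populations*: an
   implicit solver tolerates state noise at the absolute-tolerance level,
   and noise-level cell densities seeded in regions the cells cannot
   physically reach would otherwise grow exponentially wherever conditions
   are favourable. The effect is dramatic in the single-population
   experiments: acid diffuses freely across the intact-matrix wall and
   clears the stroma behind it, so without the floor a spurious
   tolerance-level tumour population ignites beyond a barrier that blocks
   all physical transport ($D = 0$ exactly), and the front "tunnels"
   through the wall. The floor corresponds to about $10^{-6}$ of carrying
   capacity — far less than one cell per grid cell — and lies four orders
   of magnitude below the front-detection threshold. It must exceed the
   absolute tolerance to be effective (the constructor warns otherwise).

Choosing $10^{-6}$ is a compromise: much smaller and integrator noise
(at tolerances down to $10^{-8}$) can cross it; much larger and it would
begin to interfere with the genuine low-density leading edge of pulled
fronts. Measured front speeds at the default configuration changed by less
than $10^{-4}$ per unit time when the floor was introduced.

### Problem sizes and tolerances used by the checks

The test-suite and the acceptance script run the reference 200-point grid
for the single-population and speed experiments with tolerances of
$10^{-8}$ (the stall positions agree with $10^{-10}$ runs to well below the
grid spacing), and the 20×20 competition sweep on a 100-point grid, which
resolves every qualitative feature of the full-resolution map while keeping
the sweep to a few minutes. Property tests (convergence order, operator
oracles, Jacobian checks) use grids of 12–101 points.

## Homogeneous steady states and invasion scenarios

`steady_states()` enumerates the equilibria of the reaction kinetics in
closed form — healthy tissue SS0 $(1,0,0,0,M^*)$, the monocultures SS1
$(0,1,0,1,M^*)$ and SS2 $(0,0,1,0,0)$, tumour-phenotype coexistence SS3,
acid-producers with stroma SS4, matrix-degraders with stroma SS5 (never
feasible when $c_S>1$), and the three-population state SS6, which
degenerates to a one-parameter family exactly at
$(c_{M,A}, c_{A,M}) = (1,1)$. Stability is classified numerically from the
analytic Jacobian (`kinetics_jacobian()`, verified against finite
differences); the symbolic closed forms only enter as residual checks
(`reaction_terms()` must vanish at every feasible state) and as test
oracles.

States that retain matrix (SS0, SS1, SS4) have a structurally free matrix
component: with no degraders present, nothing in the model responds to a
matrix perturbation (the $M$ column of the Jacobian vanishes), so these
states carry an exact zero eigenvalue and are at best marginal. The
`stability_non_ecm` column reports the classification restricted to the
$(S, T_A, T_M, L)$ subspace, which is the scientifically meaningful label.

The competition plane splits into four invasion scenarios
(`classify_regime()`): stable coexistence (both $c<1$, SS3 attracts and the
phenotypes invade together), exclusion of the acid-producers
($c_{M,A}>1>c_{A,M}$, encapsulation), exclusion of the matrix-degraders
($c_{A,M}>1>c_{M,A}$, transient invasion), and bistability (both $>1$).

`critical_competition()` bisects the leading non-matrix eigenvalue to
locate stability exchanges. Along the symmetric path
$c_{M,A}=c_{A,M}$ the SS3 exchange is exactly at 1, as is the SS1 onset in
$c_{A,M}$. A subtlety worth knowing: along the $c_{M,A}$ axis with
$c_{A,M}$ fixed at 0.5, the *stroma-reinvasion* eigenvalue
$1-\delta T_A^*$ crosses zero first — coexistence produces too little acid
to hold the stroma off once $T_A^* < 1/\delta$ — so the exchange sits at
$(\delta-1)/(\delta-\tfrac12) \approx 0.9583$ for the default
$\delta = 12.5$, slightly below the competition threshold. The often-quoted
"SS3 is stable iff both coefficients are below 1" is therefore exact only
away from that corner of the plane; the bisection reports the true
exchange, and the tests pin it to the closed form above.

```{r steady-states}
steady_states(dimensionless_params(c_MA = 0.5, c_AM = 0.5))[,
  c("label", "S", "T_A", "T_M", "L", "feasible", "stability",
    "stability_non_ecm")]
critical_competition(dimensionless_params(), "SS3", "symmetric")
```

## Metrics

* `front_position()` — default: the largest $x$ where the species density
  still reaches $\varepsilon = 10^{-2}$, linearly interpolated. Front
  definitions built on the time-derivative profile are notationally
  ambiguous (an extremum over $x$ of $\partial_t T$ is a value, not a
  position, under a literal reading); the package therefore uses the robust
  threshold crossing as its default and offers the derivative-extremum
  location (`method = "max_rate"`) as an alternative, reporting both in
  sweep outputs. An absent population returns `NA`, deliberately distinct
  from a front at 0.
* `tumour_mass()` — trapezoidal $\int_0^1 (T_A + T_M)\,dx$, exact on
  piecewise-linear fields.
* `small_population_flag()` — species with $\int T_i\,dx < 0.1$ (strict)
  are flagged for exclusion from sweep summaries, since metrics computed
  from near-extinct populations are numerically fragile.
* `invasion_speed()` — front displacement between two snapshots;
  `to_dimensional()` converts with the 11.57 days / 2.24 cm scales.

## Experiments

* `run_single_population()` (default $t_{end}=10^4$): in isolation neither
  phenotype invades. The acid-producers clear the stroma but stall against
  the intact-matrix wall at $x \approx 0.3$; the matrix-degraders open the
  matrix but are confined by stroma to $x \approx 0.2$. These two numbers
  are recomputed by `scripts/acceptance.R`.
* `run_competition_sweep()`: the Cartesian product of competition values,
  one record per combination (both front constructions, mass, per-species
  integrals, disregard flags, regime label; failures are recorded
  per-record, never fatal).
* `run_snapshot_experiment()`: one combination with stored snapshots and a
  qualitative outcome label. Documented classification constants:
  extinction means a species integral below $10^{-3}$ at the final time;
  halted means front displacement below 0.01 over the final 10 time units.
* `run_perturbation_experiment()`: in the bistable regime the mixed front
  is structurally unstable — away from the front the phenotypes reduce to
  a symmetric two-species competition system whose coexistence point is a
  saddle. Identical seeding invades; multiplicative noise of amplitude
  $10^{-2}$ (seeded, recorded) or a small spatial offset sends the
  populations into separated, parapatric configurations. Separation is
  declared when the profile overlap $\int \min(T_A,T_M)\,dx / (\mathcal{M}/2)$
  falls below 0.2 and both species survive.
* `run_kappa_sensitivity()`: repeats a reduced sweep across matrix
  degradation rates and reports the front-map asymmetry statistic (mean of
  $x_f(a,b)-x_f(b,a)$ over pairs $a<b$ below 1). The asymmetry is negative
  — the invaded distance suffers more from competitiveness of the
  acid-producers than of the degraders, because matrix removal is the
  bottleneck at the default $\kappa$ — and it responds to $\kappa$.

## What the simulated conditions do and do not show

Everything here is synthetic: the model is a deliberately minimal caricature
in one spatial dimension with two discrete, non-evolving phenotypes.
Passing tests demonstrate internal correctness (the discretisation
converges at second order, equilibria and stability match closed forms,
experiment outcomes match the linear analysis), not clinical validity. In
particular the model omits matrix regeneration, acid degradation of the
ECM, haptotaxis, angiogenesis, phenotypic plasticity and all 2-D/3-D
geometry effects; domain truncation means runs are only meaningful while
the front is away from the right boundary (the drivers' default horizons
respect this). The measured cooperative front speed at the default
parameters is about 0.0067 per unit time — roughly 0.5 cm/year — which is
at the lower edge of clinically quoted invasion speeds; the unobstructed
Fisher speed $2\sqrt{\rho_T \Delta_T} \approx 0.0126$ (0.9 cm/year) is an
upper bound that the matrix obstruction roughly halves.

## Known limitations

* The extinction floor is a modelling device; outcomes for genuinely tiny
  populations (below $10^{-6}$ of capacity) are not meaningful.
* Threshold fronts advance in small lurches on coarse grids as the leading
  edge crosses grid cells; speeds measured over short windows inherit that
  granularity.
* The degenerate line $c_{M,A} c_{A,M} = 1$ (vanishing SS3 denominator) is
  reported as infeasible-with-note rather than resolved analytically,
  except at exactly $(1,1)$ where the SS6 family is returned.
* Bisection assumes a single sign change of the leading eigenvalue on the
  search interval; paths with no exchange return `NA` with a message.
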