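---
title: "Stress-based hemolysis model optimization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-based hemolysis model optimization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemopso)
```

## The problem

Blood-contacting devices such as ventricular assist pumps expose red blood
cells to supra-physiological shear stresses, releasing hemoglobin into the
plasma (hemolysis). Flow simulations predict this damage in the design loop
with a stress-based power law,

$$H(\tau_s, t) = C\,\tau_s^{\alpha}\,t^{\beta},$$

where $H$ is the released-to-total hemoglobin ratio, $\tau_s$ an equivalent
scalar stress in Pa, $t$ the exposure time in s, and $(C, \alpha, \beta)$
empirical constants. Published constant sets disagree with measurements by
up to orders of magnitude outside the simple laminar flows they were fitted
in. `hemopso` implements a desk-scale version of a calibration pipeline for
these constants: a solver-decoupled hemolysis evaluator, two fitness
objectives against experimental data with uncertainty dead-bands, a
multi-objective particle swarm optimizer (MOPSO), and a principal-component
summary of the near-optimal constant sets.

Flow solving itself is out of scope. The pipeline starts from a solver
*export* — one row per finite volume with cell volume and effective stress —
and the package ships analytic (Hagen–Poiseuille) and synthetic (lognormal)
generators that emulate such exports with known ground truth, so every stage
is testable without CFD.

## Hemolysis evaluation

For a statistically steady flow the linearized hemolysis value
$H_L = H^{1/\beta}$ satisfies a volume-integral identity, discretized as

$$\mathrm{MIH_{num}} = \left[\frac{1}{Q}\, C^{1/\beta} \sum_k
\tau_{s,k}^{\alpha/\beta}\, \Delta V_k \right]^{\beta} \times 10^6,$$

with $Q$ the flow rate. The MIH (modified index of hemolysis) is the common
experimental scale ($H \times 10^6$); its experimental counterpart follows
the ASTM F1841-97 loop formula implemented in `mih_experimental()`.

Numerical choices:

* **Log-domain arithmetic everywhere.** The optimization domain spans
  $C \in [10^{-30}, 10^{-5}]$ and $\alpha, \beta \in [0.1, 20]$; naive
  powers under- or overflow (the best mathematical-domain constant set,
  FT-M with $C = 4.256\times10^{-24}$, $\alpha = 10.286$, is unusable
  inside flow solvers for exactly this reason). The cell sum is a
  log-sum-exp over cells with $\tau_k > 0$; zero-stress cells are skipped
  because the integrand vanishes there for $\alpha > 0$.
* **Deterministic reduction.** Sums run in the stored cell order through
  R's long-double accumulator; permutation of cells changes the result by
  less than $10^{-12}$ relative, and a fixed seed makes entire optimizer
  runs bit-reproducible.
* **No transport equation.** The Eulerian transport formulation is not
  solved; for statistically steady flows it agrees with the volume integral
  to about 1 %, and the equivalence is covered in the tests by the
  plug-flow closed form $\mathrm{MIH} = 10^6 C \tau^\alpha (V/Q)^\beta$.

Effective stresses for RANS exports combine the mean-field strain rate with
the modeled turbulent dissipation,
$\tau_{s,\mathrm{eff}} = \sqrt{2\mu^2\overline{S_{ij}S_{ij}} + \rho\mu\,\varepsilon_\mathrm{mod}}$
(`effective_stress()`), reducing to $\mu\sqrt{2 S_{ij}S_{ij}}$ in the
laminar limit.

## Fitness objectives

Each operating point carries a measured MIH with a symmetric uncertainty.
The per-point error is zero inside the uncertainty band (inclusive bounds —
the published inequalities are strict, but equality is measure-zero and
inclusive bounds avoid spurious edge failures) and otherwise

$$\xi = \left|\frac{1}{|\ln(\mathrm{MIH_{num}}/\mathrm{MIH_{exp}})| + 1} - 1\right|,$$

a bounded error that tends to 1 as the prediction ratio goes to 0 or
$\infty$. The log-ratio always uses the central experimental value, and
lower bounds that would be negative (one nozzle point is $0.02 \pm 0.13$)
are clamped to zero, so any prediction below the upper bound is in-bounds
there. The two swarm objectives are the mean error $\eta$ over all points
and the modified correlation $r = |\mathrm{Pearson}(A, B) - 1| \in [0, 2]$
between predicted and central measured MIH (raw values, not
log-transformed; sample $N-1$ normalization). A degenerate sample (zero
variance) returns the worst value 2 with a warning instead of failing, so
an optimization run survives constant-prediction particles. Particles are
ranked by the scalar $F_n = (\eta + r)/2$.

## The optimizer

The MOPSO searches $(\ln C, \alpha, \beta)$ — $C$ spans 25 decades, so its
logarithm is the natural coordinate — inside either the wide "mathematical"
box or the narrow "literature" box around the published constants
(`domain_bounds()`). Updates use the constriction form
$v' = \omega v + c r_1 (p - x) + c r_2 (g - x)$ with
$\omega = 1/(\varphi - 1 + \sqrt{\varphi^2 - 2\varphi})$, $c = \omega\varphi$,
$\varphi = 2.01$, merged learning factors, per-component uniform $r_1, r_2$,
and *no mutation operator*. Out-of-box components are clamped to the bound
with velocity maintained. Non-dominated particles accumulate in a bounded
repository; an adaptive hypercube grid (repository extent per objective,
1 % padding, 50 bins per dimension by default) drives roulette-wheel leader
selection with weight 1/occupancy and random pruning from the fullest cells
when capacity is exceeded. Personal bests are replaced on dominance and by
a fair coin on mutual non-dominance.

Design decisions worth recording:

* **Synchronous phases.** Each iteration evaluates the whole swarm, updates
  the repository and grid, then selects leaders and moves all particles —
  the literal reading of the published algorithm flowchart. An asynchronous
  per-particle variant was tried first and collapsed swarm diversity
  noticeably earlier on degenerate two-point problems.
* **Leader weighting and pruning** follow the standard Pareto-archive
  scheme (inverse occupancy; the source publication states only the pruning
  side explicitly).
* **Velocity initialization** is uniform in $\pm(UB - LB)$ per component;
  the source states only that initial velocities are randomized.
* **Slow tails are expected.** $\varphi = 2.01$ sits close to the edge of
  second-moment stability, so single-optimum refinement reaches $\sim10^{-2}$
  after 200 iterations and $\sim10^{-3}$ after 400; tests assert
  accordingly.

## The constant line

Near-optimal constant sets do not cluster at a point: they align along a
line in $(\ln C, \alpha, \beta)$. `fit_line()` keeps particles with
$F_n$ below a threshold (default 0.5), and returns the centroid plus the
leading principal axis of their covariance; the unweighted subset is used
(no fitness weighting). PCA directions are sign-ambiguous, so the
convention is a negative $\ln C$ component (matching the published line,
available as `ft_line()`), falling back to a positive dominant component
for directions orthogonal to $\ln C$.

For *uniform-stress* operating points the zero-error set is available in
closed form: each point constrains the constants to the plane
$\ln C + \alpha\ln\tau + \beta\ln t = \ln(\mathrm{MIH}\times10^{-6})$, and
two distinct points intersect in a line whose direction is the cross
product of the plane normals $(1, \ln\tau_i, \ln t_i)$
(`analytic_solution_line()`). This is the independent oracle for the
multi-modal solution structure: a swarm run on two synthetic uniform-stress
points recovers a repository whose fitted PCA line is parallel to the
analytic one. The shipped oracle uses the literature search domain and two
well-separated conditions (10 Pa for 2 s; 500 Pa for 5 ms): in the
25-decade mathematical box the swarm still finds the zero-error region but
samples only a short segment of it before diversity is exhausted, which
degrades the fitted direction — a known limitation of mutation-free PSO on
line-shaped optima, not of the PCA step.

## Synthetic data: what it emulates, what it does not

`gen_lognormal_field()` draws per-cell stresses from a lognormal
distribution — device flow exports are right-skewed with stresses roughly
0.1–1000 Pa — with equal cell volumes, defaulting to $10^4$ cells (large
enough to exercise the log-sum-exp path, small enough for desk-scale
optimization). `poiseuille_field()` discretizes laminar pipe flow into
annuli with exact volumes, providing the convergence oracle against the
closed-form radial integral. `gen_experiment()` produces experimental
records from a declared ground-truth constant set with multiplicative
lognormal noise (MIH is positive and spans decades across the fixture
tables) and relative uncertainty bands; with zero noise the truth scores
$\eta = 0$ with all points in bounds, closing the recovery loop.

The synthetic recovery study uses four fields whose log-stress levels span
the capillary-tube-to-pump range (medians 5, 30, 80 and 200 Pa at flow
rates 0.3–7 l/min), with ±10 % bands. What a green recovery test
establishes: the evaluator, objectives and optimizer are mutually
consistent and can locate a feasible zero-error constant set. What it does
not establish: anything about real CFD stress fields — the published
per-device fitness values depend on unpublished simulation exports and are
shipped only as reference fixtures (`reference_fitness_table()`), not
recomputed.

## Degenerate inputs and tolerances

* Zero stress or zero exposure time give $H = 0$; an all-zero field gives
  MIH 0 and $\xi = 1$ against any record whose band excludes 0.
* Bands are inclusive; a prediction of exactly 0 outside a band scores the
  limit error 1.
* Pearson on fewer than two points, or with zero variance, is handled as
  the worst correlation (2) with a warning.
* Uniform-field agreement with the closed form and stress-scaling
  homogeneity hold to $10^{-9}$ relative across both search domains
  including the corner constants; the Poiseuille discretization at 400
  annuli is within 0.5 % of the continuum integral.
* Comparisons against printed two-decimal table values use decimal
  half-up rounding with a $10^{-9}$ representation guard
  (`round_half_up()`), because binary doubles store values like 0.425
  marginally below the decimal half.

## Known limitations

* The capillary-tube geometry (radius, length) is not given in the source
  text; Poiseuille defaults are illustrative stand-ins, not
  reconstructions.
* The published line's printed parameter range $s \in [-10, 70]$ exits the
  mathematical search box beyond $s \approx 45$; containment tests cover
  the verified sub-range.
* Without mutation, the swarm's coverage of extended optimal sets depends
  on pre-collapse diversity; repositories from single runs under-sample
  long solution lines in very large domains.
* The experimental fixture records ship without stress fields, so
  published per-device fitness values can be compared but not recomputed.
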