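---
title: "Global curve fitting with shared parameters and analytic gradients"
author: "simulfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global curve fitting with shared parameters and analytic gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simulfit)
```

## The problem

Experiments in systems biology are rarely one curve at a time.  A microbial
growth assay repeated across conditions yields a family of time series in
which some quantities are physically the same in every run (the carrying
capacity of the medium, the shape of the growth law) while others vary per
run (the inoculum size) or vary in a structured way (one growth rate per
treatment group).  Fitting each curve separately wastes the shared
information and can make a wrong model look acceptable; the statistically
correct approach is a *global* (simultaneous) least-squares fit in which
every observation constrains the parameters it actually depends on.

simulfit implements that machinery for models given either as closed-form
expressions or as initial value problems of ordinary differential equations,
with three ingredients that make the approach practical:

1. an explicit **fit topology** assigning each (dataset, parameter) slot a
   sharing role,
2. smooth **parameter transforms** so bound constraints never produce
   discontinuities, and
3. **analytic gradients** everywhere — symbolic differentiation for
   expressions, forward sensitivity equations for ODEs — so L-BFGS can
   handle tens of free parameters efficiently.

## The model behind the worked example

The shipped example is generalized-logistic (Richards) growth,

$$N(t) \;=\; K\left[\,1 - \Bigl(1 - (K/N_0)^{\nu}\Bigr)
  e^{-r\nu t}\right]^{-1/\nu},$$

with carrying capacity $K$ (same units as $N$), initial value
$N_0 = N(0)$, growth rate $r$ (1/time), and growth curvature $\nu$
(dimensionless; $\nu = 1$ is the standard logistic).  The same model is
available through its differential form
$\mathrm{d}N/\mathrm{d}t = r N\bigl[1 - (N/K)^{\nu}\bigr]$, which the
package treats as an ODE model with $N_0$ an ordinary, fittable parameter;
the two routes agree to solver tolerance and are cross-checked in the test
suite.

## Sharing roles and the packed parameter vector

Every free parameter of every model, for every dataset bound to that model,
is one *slot*.  A slot's role is one of:

* **model** — one value shared by all datasets bound to the model;
* **data** — an independent value per dataset (the default, equivalent to
  separate fits when used everywhere);
* **detached** — tied to a named standalone parameter; any slot of any
  model may tie to the same name, which is how arbitrary sharing patterns
  (including sharing across different models) are expressed;
* **constant** — fixed at a value and excluded from fitting.

The free parameters are packed into one flat vector in a deterministic
order (model-shared identities sorted by model then parameter, detached
names lexicographically, then per-dataset slots by dataset order and
parameter name), so results files are reproducible and diffable.  In the
worked example — six curves, $K$ and $\nu$ model-shared, $N_0$ per dataset,
$r$ tied to detached names `rA`/`rB` per triplet — the packed vector has
$1 + 1 + 2 + 6 = 10$ entries.

## Bounds via transforms

Most growth parameters are physically positive, so unannotated parameters
default to the bound $(0, \infty)$.  Rather than clipping, every bounded
parameter $b$ is represented by an unconstrained hidden variable
$\tilde b$:

* positivity (and general lower bounds $l$): $b = l + e^{\tilde b}$;
* upper bounds $u$: $b = u - e^{-\tilde b}$ (kept increasing so all
  transforms are orientation-consistent);
* intervals $(l, u)$: $b = l + (u - l)\,\operatorname{logistic}(\tilde b)$.

The optimizer never sees a boundary, the objective stays differentiable,
and gradients chain through the strictly positive factor
$\mathrm{d}b/\mathrm{d}\tilde b$.  The exponential branch clamps
$\tilde b$ to $[-700, 700]$ before exponentiation because L-BFGS line
searches occasionally probe extreme points; at such extremes the map
saturates at the representable floating-point neighbour of the bound
rather than overflowing.  Annotations use a compact `R(lo, hi)` / `C(value)`
notation (`R(0, inf)` positive, `R(-inf, inf)` unbounded, `C(10)` a
constant).

## Gradients

For expression models the package parses the body into a small whitelisted
expression language (`+ - * / **`, unary minus, `exp log sqrt sin cos tan
abs`) and differentiates the tree symbolically; derivatives are exact up to
floating point.  Two deliberate conventions: `0**0` evaluates to 1, and
the derivative of `abs` at 0 is taken as 0 (a subgradient).  Domain
violations (`log` of a non-positive value, `0**negative`, fractional powers
of negatives) are hard errors rather than silent `NaN`s, so optimizer
diagnostics stay meaningful.

For ODE models the package integrates the forward sensitivity system

$$\frac{\mathrm{d}S}{\mathrm{d}t} \;=\;
  \frac{\partial f}{\partial y}\,S + \frac{\partial f}{\partial \theta},
  \qquad S(t_0) = \frac{\partial y_0}{\partial \theta},$$

alongside the state, with both Jacobians taken symbolically from the
right-hand-side trees.  When an initial condition *is* a parameter, its
column of $S(t_0)$ is the corresponding indicator vector, which is what
makes $N_0$ estimable through the ODE route.  Output transforms (a custom
function of states, parameters, and event values) are chain-ruled on top of
$S$.

The per-dataset gradient of the pooled sum of squared residuals is then
accumulated across slots: each packed entry receives the *sum* of
$\partial\mathrm{SSE}/\partial(\text{natural value})$ over all slots
sharing its identity, times the transform factor.  `check_gradient()`
audits the assembled gradient against central finite differences and is
exercised at every level of the test suite.

## Numerical choices

* **Integrator**: `deSolve`'s `lsoda` with `rtol = 1e-6`, `atol = 1e-9`
  by default, reporting exactly at the requested times.  An adaptive
  multi-step code was chosen over a fixed explicit Runge–Kutta pair because
  it is robust across the stiffness range users feed in and is the
  established default in the R ecosystem.
* **Events**: conditions are scanned on the requested grid refined to at
  least 257 points and each first crossing in the stated direction is
  located by bisection on a cubic-Hermite dense representation of the
  trajectory, to a time tolerance of $10^{-9}(t_{\max}-t_0)$.  The
  sensitivity snapshot attached to an event is $S$ interpolated at the
  located time; the implicit dependence of the event *time* on the
  parameters is deliberately not propagated (the snapshot is what the
  steady-state-normalization use case needs), and the finite-difference
  tests bound the consequences for the shipped examples.  A terminal event
  freezes all later outputs at the event-time value.
* **Optimizers**: L-BFGS (`optim`, memory 10, projected-gradient tolerance
  `1e-8`, up to 1000 iterations) on the hidden vector with analytic
  gradients is the default.  The gradient-free fallback is Nelder–Mead,
  restarted from its own incumbent (up to 100 times, stopping when the
  objective improves by less than $10^{-10}$ relative) because a single
  simplex run stalls on ten-parameter problems; it reliably reaches the
  L-BFGS optimum at the cost of orders of magnitude more function
  evaluations.
* **Failure policy**: if an ODE integration breaks down or an expression
  leaves its domain during a line search, the objective returns the finite
  penalty $10^{12} + \lVert \tilde\theta - \tilde\theta_0\rVert^2$ (with
  the gradient of the distance term) instead of throwing, steering the
  search back toward the starting point.
* **$R^2$ pooling**: the global coefficient of determination uses the
  pooled mean over all points of all datasets in $SS_{\mathrm{tot}}$ — the
  simplest convention for a simultaneous fit, and the one all reported
  global values use.  Per-dataset values use each dataset's own mean.

## The synthetic generator

`simulate_growth_curves()` produces the worked example: Euler–Maruyama
integration of the Langevin equation

$$\mathrm{d}N = r N\left[1 - (N/K)^{\nu}\right]\mathrm{d}t
  + \sigma N\,\mathrm{d}W$$

with $K = 10$, $\nu = 0.5$, $\sigma = 0.01$, growth rates $0.2$ (first
triplet of curves) and $0.1$ (second triplet), initial values
$N_0 \in \{0.01, 0.02, 0.1\}$ within each triplet, followed by additive
Gaussian measurement noise with SD $0.1$.  The measurement grid is 101
equispaced points on $t \in [0, 100]$ with Euler–Maruyama step
$\mathrm{d}t = 0.01$: the horizon was chosen so the slowest curve
($r = 0.1$, $N_0 = 0.01$) approaches its plateau closely enough that $K$
is identifiable, and the step is two orders of magnitude below the
measurement spacing.  Each curve draws from its own substream of the root
seed, so adding a curve never perturbs previously generated ones; negative
excursions are clipped to a tiny positive floor with a reported count.

What the generator deliberately does *not* emulate: non-Gaussian or
heteroscedastic measurement error, irregular sampling, missing data,
plate-reader artefacts (lags, drift), or correlations between curves.
Passing tests therefore demonstrate correctness of the fitting machinery
under the stated noise model, not robustness to the full mess of real
growth data.

## Initial guesses

The shipped example model carries default guesses of magnitudes typical
for normalized microbial growth data ($K = 5$, $N_0 = 0.05$, $\nu = 1$,
$r = 0.3$); unannotated parameters elsewhere default to a guess of 1
(midpoint for interval bounds).  As with any nonlinear least-squares
problem, guesses matter: they are part of the configuration, can be set per
identity (e.g. `rA`) or per parameter name, and must lie strictly inside
their bounds — a guess on or outside a bound is rejected by name before
any iteration.

## Known limitations

* **$r$–$\nu$ identifiability.**  On the worked example's grid the growth
  rate and the curvature are strongly correlated: restarting the optimizer
  at the generating values reproduces the same minimum, yet the recovered
  $r$ can sit roughly 10% from truth on individual realizations while the
  fit quality is excellent.  This is a property of the Richards model under
  this design, not of the optimizer; recovery of $K$ is tight.  The test
  suite asserts recovery at the level this design supports (median within
  10% for the rates and $K$ over ten simulation seeds).
* Event sensitivities omit the event-time dependence (see above).
* No stiff/implicit tailoring beyond what `lsoda` switches to internally,
  no adjoint gradients (forward sensitivities scale with the parameter
  count, fine at the tens of parameters targeted here), and no uncertainty
  quantification — the fit reports estimates, objective, and $R^2$ only.

## Problem sizes used by the tests

The test suite and the acceptance script regenerate everything they need:
six 101-point curves per simulation seed, ten seeds for the stochastic
checks, twenty random parameter draws for the expression/ODE equivalence
and sensitivity audits, and 500 Euler–Maruyama replicates for the
generator's ensemble-mean check.  A full run fits the three sharing
arrangements (10, 9, and 24 free parameters) once per seed.

## A compact example

```{r example, eval = FALSE}
curves <- simulate_growth_curves(seed = 1)
top <- growth_example_topology(curves, sharing = "detached")
fit <- simulfit(top)
summary(fit)
plot(fit)
```
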