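---
title: "Modelling patient flows across China's three-tier hospital system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling patient flows across China's three-tier hospital system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tierdyn)
```

## The model

Chinese hospitals are graded into first-, second- and third-level
institutions (FLH, SLH, TLH). Patients choose freely among them, and many
bypass their local tier for a higher one. `tierdyn` models the monthly
visit counts $x(t)$, $y(t)$, $z(t)$ of the three tiers as

$$
\begin{aligned}
\dot x &= -\tfrac{r_f}{m_f}x^2 + r_f x - \alpha x - \eta x - c_f x,\\
\dot y &= -\tfrac{r_s}{m_s}y^2 + r_s y + \alpha x - \beta y - c_s y,\\
\dot z &= -\tfrac{r_t}{m_t}z^2 + r_t z + \eta x + \beta y - c_t z.
\end{aligned}
$$

Each tier grows logistically: the per-visit growth rate falls linearly
from its inherent value $r$ at zero load to $0$ at the capacity $m$
(`logistic_rate()`). Visits leak out of every tier at a churn rate $c$
(deaths, abandoned treatment), and "leapfrog" transfers move visits up the
hierarchy at rates $\alpha$ (FLH→SLH), $\beta$ (SLH→TLH) and $\eta$
(FLH→TLH). Time is in months; counts are in units of 10,000 visits per
month, the scale of the national statistics the reference parameters were
estimated from.

Two structural facts drive everything else:

* **Triangular coupling.** $\dot x$ depends only on $x$, and $\dot y$ only
  on $(x, y)$: patients flow up the tiers, never down. The Jacobian is
  lower triangular, so all eigenvalues are real, and the first-tier
  equation is a scalar logistic ODE with effective rate
  $\rho = r_f - \alpha - \eta - c_f$ whose exact solution
  (`closed_form_x()`) serves as an independent oracle for the integrator.
* **Forward invariance.** On each face of the non-negative octant the flow
  points inward or along the face, so trajectories started at non-negative
  counts stay non-negative.

## Equilibria and stability

Setting the right-hand side to zero gives four equilibria
(`all_equilibria()`): the empty state $E_1 = (0,0,0)$; $E_2$ with patients
only at third-level hospitals; $E_3$ with the two upper tiers occupied;
and the positive equilibrium $E_4$ with all tiers occupied. Their
existence is governed by three strict inequalities
(`existence_conditions()`): $H_1: r_t > c_t$, $H_2: r_s > \beta + c_s$,
$H_3: r_f > \alpha + \eta + c_f$ — each tier persists on its own only if
its inherent growth beats its total outflow. The third-tier coordinate of
$E_3$ and $E_4$ is the positive root of a quadratic balance between
logistic growth, churn, and leapfrog inflow (`positive_root_z()`); we
compute it from the quadratic formula and cross-check it against a numeric
root-finder in the tests.

Because the Jacobian (`visit_jacobian()`) is lower triangular, local
stability reduces to the signs of its diagonal at the equilibrium
(`classify_equilibrium()`). The four regimes $H_4$–$H_7$ partition
parameter space off their boundaries, and exactly one equilibrium is
stable in each — from the empty state when every tier's growth is beaten
by its outflow ($H_4$), up to $E_4$ whenever $H_3$ ($= H_7$) holds. Non-hyperbolic cases (an eigenvalue within
`1e-10 * max(r)` of zero) are reported as `"marginal"` with no stability
claim, since the linearization decides nothing there. On the existence
boundaries the merging equilibrium is reported with `exists = FALSE`, a
`marginal` flag, and its well-defined limiting coordinates.

At the packaged reference parameters (`reference_params()`, estimated from
the 2011–2018 national monthly series), $H_1$ fails while $H_2, H_3$ hold:
third-level growth is below churn, and TLH visits are sustained purely by
leapfrog inflow. The package computes the stable positive equilibrium

```{r}
equilibrium("E4", reference_params())
```

i.e. about 21.3, 110.4 and 182.0 million visits/month. Long-time
integration from interior states converges to the same point, which the
tests assert to relative 1e-3. A caveat for readers comparing numbers:
this parameter vector has circulated together with a steady-state triple
(4555.04, 13028.5, 18978.6), which does **not** satisfy the equilibrium
equations at these parameter values — direct evaluation of the closed
forms, confirmed by integration, gives (2126.3, 11041.3, 18203.3). The
package reports what the parameters imply and does not force agreement
with the quoted triple.

## Numerical choices

* **Integrator**: adaptive Dormand–Prince 4(5) (`deSolve`), `rtol = 1e-8`,
  `atol = 1e-10`; the quadratic field is smooth and non-stiff at monthly
  rates. The right-hand side is also implemented in C (`src/visits.c`) —
  bit-compatible with the R implementation, roughly 15× faster, and the
  default path; `compiled = FALSE` selects the R field.
* **Steady-state detection**: integrate in 100-month chunks until the
  scaled speed $\lVert f(s)\rVert / \max(m)$ drops below `1e-8` (default),
  up to `t_max = 2000` months; non-convergence is a flag, not an error.
* **Sweeps** (`sweep_parameter()`, `capacity_sweep()`) default to a
  600-month horizon; source analyses of this system never state their
  simulation horizon or initial state, so these are conventions chosen to
  reach within solver tolerance of the attractor, not reproductions.
* **Degenerate cases**: $\rho = 0$ in the first-tier closed form uses the
  separable solution $x_0/(1 + (r_f/m_f)x_0 t)$; leapfrog rates are
  admitted at exactly 0 (the model is usually stated with $\alpha, \beta,
  \eta > 0$) so decoupled tiers are expressible in tests.

## Fitting and what is actually identifiable

`fit_visits()` minimizes the pooled sum of squared residuals between an
observed Jan–Nov monthly series and the integrated model over all twelve
parameters, with the initial state fixed to the first observation triple.
A single pooled SSE (and pooled $R^2$ about the pooled grand mean,
`r_squared()`) is used because tier-specific weighting is a modelling
choice the data do not force; an optional inverse-variance weighting flag
exists but defaults off. Optimization is bounded Levenberg–Marquardt
(`minpack.lm`) on log-parameters — positivity for free and a common
relative scale — with a finite-difference Jacobian (`epsfcn = 1e-8`, so
difference steps sit well above the integrator's error floor) and seeded
multi-start jitter (default 8 starts, seed 20220426).

The central caveat: **the trajectories depend on the twelve parameters
only through nine combinations** — per tier the curvature $r/m$ and the
net linear rate ($r_f-\alpha-\eta-c_f$, $r_s-\beta-c_s$, $r_t-c_t$), plus
$\alpha$, $\beta$, $\eta$, which are pinned by the inflows they generate.
Within each tier the triple $(r, m, c)$ is determined only up to a
one-parameter family, so the zero-residual set is a 3-dimensional ridge
and *no* estimator can recover all twelve parameters from visit series
alone. `fit_visits()` therefore also reports
`identifiable_combinations()`: on noiseless synthetic data these are
recovered to machine-level accuracy while raw per-tier triples retain the
initial guess's offset along the ridge. Under noise the z-equation adds a
practical (not just structural) weakness: with a small $r_t$ the
third-tier curvature is a percent-level effect, and $\eta x$ and $\beta y$
are nearly collinear inflows, so even $\eta$ and $\beta$ separate poorly.
This is worth remembering when interpreting any published twelve-parameter
vector for this model — including the reference set, whose $r_t < c_t$ is
exactly the kind of ridge endpoint the fit produces.

## The synthetic-data generator

`generate_series()` emulates the study conditions of the national series:
integrate the model from an early-2010s-scale initial state (default
`c(1150, 6700, 10300)`, about 60% of the 2019 monthly tier averages in
`hospital_resources_2019()`), sample months 1–11 of each of 8 years
(December is unreported in the source statistics), and apply multiplicative
Gaussian noise (default `noise_sd = 0.02`; multiplicative because tier
scales differ by an order of magnitude). An optional 12-month sinusoid
(`seasonal_amp`, phase 0) exists because real series show seasonality the
model does not describe; it is a robustness probe, not a model of China's
actual seasonality. The generator is deterministic given its seed.

What passing tests on generated data do show: the estimator recovers
everything the model makes recoverable, at the study's sampling scheme and
noise level. What they cannot show: robustness to the unmodelled structure
of real series (seasonality, policy shocks, reporting artifacts), nor
recovery of quantities the model itself does not identify.

## Problem sizes used in the checks

The packaged verification (`scripts/acceptance.R`, `tests/testthat/`) uses
20 random parameter sets for the analytic-oracle comparison over 200
months, 100 sets for equilibrium residuals and stability classification,
25 attraction runs, and a recovery study of one noiseless fit plus 20
noisy seeds at the 8-year × 11-month × 3-tier size. Random draws span
growth rates 0.02–0.3/month, log-uniform capacities 30–30,000, churn
0.001–0.08/month and transfers 0–0.08/month, which covers all seven
existence regimes.

## Known limitations

* Local stability only; no basins of attraction or global statements.
* No seasonal forcing, demography, epidemic shocks or policy interventions
  inside the model; the generator's seasonality is observational only.
* The twelve-parameter fit is a ridge (see above); only the nine
  identifiable combinations — and anything downstream of them, such as the
  equilibria — should be interpreted quantitatively.
* December-free sampling is handled by integrating continuously and
  sampling sparsely; no imputation is attempted.
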