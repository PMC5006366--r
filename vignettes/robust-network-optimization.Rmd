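---
title: "Robust dynamic optimization of kinetic networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust dynamic optimization of kinetic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(robustoc)
```

This vignette explains the model class the package handles, the
approximations it makes, the tunable parameters that matter, and the design
decisions taken where several reasonable implementations exist. It states
no empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## Problem class

The package optimizes controls of kinetic network ODE models

$$\dot{x} = f(x, u, \theta, t), \qquad x(0) = x_0,$$

where the states are metabolite (and possibly enzyme) concentrations in mM,
the controls are either enzyme concentrations directly
(`control_kind = "direct_concentration"`) or enzyme-expression rates with
first-order enzyme turnover $\dot e = r - \lambda e$
(`control_kind = "expression_rate"`), and $\theta$ collects uncertain
kinetic parameters. Rate laws are mass action ($v = k\,S\,e$) or
Michaelis–Menten ($v = k_{cat}\, e\, S/(K_M+S)$); auxiliary integrator
states accumulate integral objectives such as the enzymatic cost
$\int \sum_i e_i\,dt$. Constraints are control bounds, per-element linear
control constraints (e.g. a shared expression-capacity budget), a total
enzyme-pool path constraint, and terminal constraints on product
concentrations.

Parametric uncertainty is stochastic: normal or uniform marginals with mean
$\theta_{nom}$ and covariance $\Sigma$, usually given as a relative
standard deviation (20 % for the linear-pathway fixture, 10 % for the
branched network). A chance constraint
$\Pr[c \ge c_{min}] \ge \beta$ is replaced by the deterministic backoff form
$\mathbf E[c] - \alpha\sqrt{\mathbf{Var}[c]} \ge c_{min}$. Under a
normality assumption on the constrained quantity, $\alpha$ is the one-sided
standard-normal quantile (0.84 / 1.28 / 1.65 / 1.96 for confidence 0.80 /
0.90 / 0.95 / 0.975); without distributional assumptions the
Cantelli–Chebyshev bound $\alpha = \sqrt{\beta/(1-\beta)}$ applies, which
is markedly conservative (4.36 at $\beta = 0.95$). Only *single* chance
constraints are supported: each probabilistic constraint is backed off
individually, and no joint probability statement is made.

## Uncertainty propagation

Three techniques estimate $(\mathbf E, \mathbf{Var})$ of terminal
functionals, each embedding an augmented dynamic system into the
optimization so that the moments respond to the controls:

* **Linearization** integrates the forward sensitivities
  $\dot S = f_x S + f_\theta$, $S(0)=0$ alongside the states
  ($(n_\theta+1)n_x$ states) and uses the first-order sandwich
  $P = S\Sigma S^\top$. It assumes the uncertainty is small relative to
  the model curvature and is restricted to (approximately) normal
  uncertainty; the constructor refuses the uniform family.
* **Sigma points** (unscented transform) integrates $2n_\theta+1$ model
  replicas at $\theta_{nom}$ and
  $\theta_{nom} \pm \mathrm{col}_i\sqrt{(n_\theta+\kappa)\Sigma}$ with
  $\kappa = 3-n_\theta$, sharing one control trajectory, and takes the
  weighted empirical moments. It is exact for affine maps and matches
  second-order Taylor accuracy otherwise.
* **Polynomial chaos expansion** of order $p$ regresses the sampled
  response on a distribution-matched orthogonal basis: probabilists'
  Hermite polynomials for the normal family, Legendre polynomials (after
  affine standardization to the $\pm\sqrt 3$ unit-variance support) for the
  uniform family. With $L = \binom{n_\theta+p}{p}$ basis terms, $n_s = L$
  model replicas are integrated; the mean is the zeroth regression
  coefficient and the variance $\sum_{j\ge1} a_j^2\,\mathbf E[\Phi_j^2]$.

Design choices in this module that the literature leaves open:

* *Matrix square root*: the lower-triangular Cholesky factor, the standard
  deterministic choice for unscented transforms; any PSD root is
  admissible. A symmetric eigendecomposition root is substituted only for
  singular $\Sigma$ (e.g. the degenerate $\Sigma = 0$ used in reduction
  tests), where Cholesky is undefined.
* *PCE collocation points*: the candidate set is the tensor grid of the
  roots of the degree-$(p+1)$ univariate orthogonal polynomial; candidates
  are ranked by joint density (ties broken by proximity to the mean, then
  lexicographically), the mean is always included, and points are accepted
  greedily while the regression matrix gains rank, stopping at $n_s = L$.
  This reproduces the property that for three normal parameters the sigma
  points are a subset of the order-2 sampling set, and it degrades
  gracefully to an over-determined least-squares design ($2L$ points) if
  the square design were singular. Parameters are standardized to
  zero-mean unit-variance coordinates before basis construction for
  conditioning; correlated $\Sigma$ is handled by the same affine
  transform.
* *Uniform marginals* are parameterized by mean and standard deviation
  (support $\theta_{nom} \pm \sqrt3\,\mathrm{std}$), so that a "10 %
  relative standard deviation" means the same second moment under both
  families.

## Backoff reformulation

Both penalty forms for robustified objectives are implemented:
$\mathbf E[J] + \alpha\sqrt{\mathbf{Var}[J]}$ (`sqrt_variance`) and
$\mathbf E[J] + \alpha\,\mathbf{Var}[J]$ (`variance`). The branched-network
fixture robustifies its enzymatic-cost objective with the *variance* form,
which is how that case study is stated in its source; the square-root form
is a one-line switch (`backoff_policy(penalty=)`). The two differ only in
the units of the penalty and the induced trade-off curvature, not in the
feasibility of the chance constraint, which always uses the square-root
form.

The normal-quantile table rounds the 95 % quantile to 1.65 following the
convention of quoting 1.645 to two decimals half-up; `qnorm(0.95)` rounds
to 1.64 under strict two-decimal rounding, and the tabulated convention is
reproduced deliberately (two-stage rounding via three decimals).

## Transcription and NLP solution

States and controls are fully discretized by orthogonal collocation:
uniform finite elements, controls piecewise constant per element, cubic
Lagrange interpolation through the element start plus the three right-Radau
nodes ($\tau = 0.155051,\ 0.644949,\ 1$), collocation equalities at the
Radau nodes, and continuity constraints between elements
($(n_{el}-1)\,n_{states}$ of them). Radau collocation is stiffly accurate
(the last node is the element end), which keeps the scheme robust on stiff
kinetics. The default is 30 elements for production runs; the bundled
tests and the acceptance script use 6–25 elements, which the grid-refinement
checks show is already within the assertion tolerances for these fixtures.
Piecewise-constant controls reproduce the on/off switching structure that
these enzyme-activation problems exhibit at their optima.

No interior-point NLP library is part of this package's dependency
footprint, so the transcribed problem is solved by a classical
augmented-Lagrangian method: the collocation equalities are eliminated by a
per-element implicit Newton solve (the same equations a simultaneous solver
would carry as constraints), exact derivatives of each element map with
respect to its entry state, controls and step length are extracted from the
factored Newton system via the implicit-function theorem and chained into
exact reduced gradients, and the bound-constrained augmented-Lagrangian
subproblems are minimized with `L-BFGS-B`. Multipliers for the inequality
constraints (robustified terminal constraints, per-element control budgets,
the enzyme-pool path constraint) are updated between outer iterations; the
penalty is increased when the violation does not shrink, and a safeguard
rejects inner steps that destroy feasibility wholesale — without it, a
cost-minimizing first pass can collapse the expression-rate fixture into a
dead state (all enzymes at zero) where the product-constraint gradient
vanishes and no local information points back. Convergence is declared at
constraint violation below 1e-6 and projected Lagrangian stationarity below
the KKT tolerance (default 1e-5), or when the objective is feasible and
stationary to the inner solver's precision.

Numerical details worth knowing:

* The per-element Newton uses a chord strategy (the Jacobian is refreshed
  only when contraction stalls) with analytic model Jacobians for the
  declarative rate laws; custom-RHS models fall back to central finite
  differences.
* The enzyme-pool path constraint $\sum_i e_i \le E_T$ is imposed at
  element end nodes (every element's terminal collocation node). For both
  fixtures it is provably inactive along feasible controls
  ($d(\sum e)/dt \le \sum r - \lambda \sum e$ keeps $\sum e \le
  \sum r_{max}/\lambda = E_T$), so the placement does not affect the
  optima; it is enforced anyway and checked in the solution report.
* Free final time is handled by scaling the element lengths with $t_f$ as
  an extra decision variable; the fixed initial expression allocation of
  the branched network ($r(0) = (0.5, 0, 0, 0)$) is realized by pinning
  the first element's control values, the natural discrete analogue under
  piecewise-constant controls.
* Nonconvexity is real (bilinear rate laws): nominal problems are solved
  from two structured starts (uniform budget split and sequential
  activation), robust problems are warm-started from the nominal solution,
  and Pareto points from their neighbour — the continuation order in which
  such problems are solved in practice.

## Pareto fronts

Two-objective trade-offs use Normal Boundary Intersection: anchor points
minimize each objective alone; objectives are normalized to $[0,1]$ with
the anchor values (the two fixture objectives have different units,
seconds versus mM·s); evenly spaced points on the segment joining the
normalized anchors launch subproblems that maximize the advance $t$ along
the quasi-normal $-(1,1)/\sqrt2$ subject to
$\tilde F(w) \le P(\beta) + t\,\hat n$ componentwise. The inequality
(rather than equality) form is deliberate: it is the continuation-friendly
variant, it cannot overshoot past the attainable set, and on the
closed-form test problem it recovers the exact front. Failed subproblems
are recorded with status `"failed"` and the front is returned partially
rather than erroring.

## Monte-Carlo validation

Candidate profiles are assessed on $N = 1000$ parameter draws (seeded, so
reports are exactly reproducible): violation counts use strict inequality
against the printed bound — ties have measure zero — and the report carries
empirical means and standard deviations of the objective and the
constrained quantity. Normal draws are *not* truncated at zero: at the
relative standard deviations used here the probability of a negative rate
constant is about $3\times10^{-7}$ per draw, and a `truncate` flag exists
for regimes where it matters. Two integration routes are available: the
per-realization stiff integrator (`lsoda`, rtol 1e-8, restarted at control
discontinuities — the default, and at least as accurate as the collocation
used in optimization) and a vectorized fixed-step RK4 batch simulator for
large ensembles (e.g. the $10^5$-sample oracle in the test suite); the two
agree to integrator tolerance on the fixtures, which is itself a test.

## What the fixtures do and do not establish

The bundled case studies are small (5 and 9 integrated states), their
uncertain parameters are few (3), independent and mildly dispersed, and
their "true" data-generating process in the Monte-Carlo assessments is the
same ODE model with perturbed parameters. Passing tests therefore
demonstrate the correctness of the propagation algebra, the transcription
and the solver on this model class — they do not establish that a 1.65
backoff yields 95 % confidence on a real pathway, where structural model
error, correlated and non-Gaussian parameter posteriors, and process noise
in the dynamics (not modelled here) all widen the gap between nominal
model and reality. The linearization technique in particular degrades when
the uncertainty is large relative to the model curvature; the Monte-Carlo
step is the arbiter and is cheap at this scale.

## Known limitations

* Rate-law grammar is limited to mass action and Michaelis–Menten;
  arbitrary kinetics enter through the documented custom-RHS escape hatch,
  which forfeits the declarative config round-trip and analytic Jacobians.
* Only single chance constraints; no joint chance constraints, no
  worst-case/minmax formulation, no measurement-feedback re-optimization.
* Fronts are limited to two objectives.
* The augmented-Lagrangian solver is a local method on a nonconvex
  problem; multi-start and warm-start defaults mitigate but do not remove
  dependence on initialization.
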