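---
title: "Adaptive S-system inference: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive S-system inference: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ssinfer)
```

# The inference problem

`ssinfer` addresses a deliberately restricted but experimentally relevant
setting: all dynamically important species are observed, and for each of
`N` samples we are given the concentration vector `x` (assumed accurate),
the measured rate of change `x'` of every species, and the rate standard
errors `sigma'`. Because rates are measured directly, a candidate rate
function can be scored without integrating differential equations — the
weighted residual

$$\chi^2 \;=\; \sum_{i=1}^{N}\sum_{\mu=1}^{J}
\left(\frac{x'_{i\mu} - X'_\mu(\mathbf{x}_i)}{\sigma'_{i\mu}}\right)^2$$

is a sum over independent samples. This is what makes the whole pipeline
run in seconds where trajectory-matching approaches need hours.

The package does **not** attempt to recover the mechanistically true
network. The fitted objects are *phenomenological*: power-law surrogates
chosen for predictive power on rate data, with complexity adapted to how
much the data can actually constrain.

# The S-system surrogate family

Each species' rate is a difference of a production and a degradation term,
both products of power laws:

$$\frac{dx_\mu}{dt} = \alpha_\mu \prod_\nu x_\nu^{g_{\mu\nu}}
 - \beta_\mu \prod_\nu x_\nu^{h_{\mu\nu}}.$$

In log space both terms are linear in their parameters, which is the
property everything else exploits. Two structural conventions:

* Parameters live in a pair of `(1+J) x J` matrices (prefactor row, then
  exponent rows), and every model carries a binary `ParameterMask` of the
  same shape. A masked-out parameter is held at 0 — prefactor 1, exponent
  0 — so the all-fixed model predicts exactly zero rate everywhere.
* Prefactors are stored as logarithms, making positivity structural.

Power laws are undefined at nonpositive concentrations. The package
raises an error (naming the offending species) rather than clamping:
a zero concentration is a modeling problem the user should see, not a
value to patch silently.

# Fitting: alternating regression, and when it needs help

`alternateFit` starts from the default model and alternates two weighted
ridge regressions: fit the production parameters against the targets
`Y = log(H + x')` holding degradation fixed, then degradation against
`Y = log(G - x')`. The weights `W = exp(Y)/sigma'` are the delta-method
inverse standard deviations of the log targets, and entries whose log
argument is nonpositive get weight exactly zero for that iteration; their
fraction is tracked per sweep in the returned diagnostics. The per-species
ridge system is solved as an augmented least-squares problem by QR
(`maskedRidgeSolve`), which tolerates the enormous dynamic range the
weights can reach where plain normal equations lose all precision.

Numerical policy, in order of importance:

* **Convergence metric.** Sweeping stops when the *linear-space* penalized
  `chi2~` changes by less than `relTol` (default 1e-2) between sweeps.
  The log-space objective the regression actually minimizes is logged too,
  but the linear-space value is what selection ultimately uses, so it is
  the one monitored.
* **Best-iterate guard.** The log-space updates are not guaranteed to
  decrease the linear-space objective; `alternateFit` therefore keeps the
  best iterate seen. When the model class cannot represent the data (low
  hierarchy levels on oscillator data) the raw alternation can run away
  exponentially — both terms inflating while chasing each other — so
  sweeping also stops once the objective exceeds the best seen by six
  orders of magnitude. The raw final iterate is still returned as
  `finalModel`, because the unguarded behavior is itself of scientific
  interest (see the experiment driver below).
* **Species failure.** If a species' weights are zero in every half-step
  of every sweep its parameters stay at defaults and the failure is
  reported, not guessed around.
* **Refinement.** The alternation is fast but, under mis-specification,
  often stalls far from the penalized maximum likelihood. The Laplace
  selection score is an expansion *around the maximum likelihood point*,
  so `selectModel` refines every candidate with `polishFit` — a BFGS pass
  on the penalized linear-space objective with analytic gradients —
  before scoring. This is a deliberate extension of the pure alternation
  scheme: without it, restricted masks are scored at arbitrary stall
  points and the selection degenerates. The alternating fit remains the
  workhorse (and the sole fitter exposed for the "fully connected"
  baseline); the polish only finishes the optimization that the score
  definition presumes.

# Selection: Laplace evidence and effective parameters

`buildHierarchy` produces strictly nested masks: degradation prefactors
plus diagonal production exponents (the 2J-parameter simplest model), then
diagonal degradation exponents, production prefactors, and off-diagonal
exponent rings at increasing neighbor distance, production before
degradation — 2J+1 levels ending at 2J(J+1) parameters. Random orderings
keep the mandatory first level and permute the remaining parameters into
groups of J, preserving the growth granularity; the hierarchy-robustness
driver (`compareHierarchies`) measures how much the ordering matters
relative to the randomness of the training data.

Each candidate is scored with

$$\mathcal{L}(M) = -\tfrac12\tilde\chi^2(P_{best})
 - \tfrac12\sum_\mu \log\lambda_\mu - \tfrac12\sum_k \log\varsigma_k^2,$$

a Gaussian estimate of the log evidence that generalizes BIC by weighting
every parameter direction with its actual curvature: sloppy directions —
small Hessian eigenvalues — cost nothing, stiff directions are charged.
The number of eigenvalues above 1 is reported as the count of *effective*
parameters. Choices that required judgment:

* **Two prior widths.** The regression ridge keeps `sigma_p = 0.1`; the
  selection score uses a wider `sigma_k = 10` (configurable). A sloppy
  direction then has curvature `1/sigma_k^2 = 0.01 << 1`, consistent with
  the eigenvalue-above-1 rule for effectiveness; with the ridge width used
  for scoring instead, *every* direction would sit at curvature 100 and
  the sloppy/stiff distinction would collapse.
* **Linear-space chi-squared in the score.** The score uses the
  linear-space residual (the quantity whose evidence we want), not the
  log-space surrogate the alternation minimizes.
* **Hessian estimation.** Central finite differences of the scalar
  objective with per-parameter steps `max(1e-4 |p|, 1e-6)`, symmetrized;
  all evaluation points are batched through one vectorized evaluator, so
  a 112-parameter Hessian costs a few matrix products rather than tens of
  thousands of R calls.
* **Eigenvalue floor at the prior curvature.** The exact Hessian of
  `chi2~/2` can never fall below `1/sigma_k^2` in any direction (the data
  term is locally convex at the optimum, the prior contributes exactly
  `1/sigma_k^2`). Finite-difference estimates of perfectly sloppy
  directions scatter around that bound, and occasionally below zero; any
  fixed tiny floor (say 1e-8) then turns each such direction into a large
  *bonus* `-log(lambda sigma_k^2)/2 > 0` — an Occam term that rewards
  adding parameters, which inverts the selection. Eigenvalues are
  therefore clipped at `1/sigma_k^2`, the analytic bound, making sloppy
  directions contribute exactly zero; the number clipped is reported.
* **Ties** go to fewer nominal parameters.

# The glycolysis benchmark generator

The synthetic-data module emulates the standard 7-species yeast glycolysis
oscillator (glucose influx, an allosterically inhibited phosphofructokinase
step, downstream mass-action reactions, membrane exchange into an external
compartment). All constants are the published values (`GlycolysisParameters`),
concentrations in mM, time in minutes; the system settles onto a stable
limit cycle with a period of about a minute.

A training set of size `N` draws initial conditions uniformly from the
published per-species ranges, integrates each forward to an independent
time uniform on `[0, T]`, and records the state and rate there. The
training horizon `T` is the difficulty dial: at `T = 5` min most samples
lie near the low-dimensional attractor; at `T = 0` the data cover the full
initial-condition box, where nonlinearities dominate. Test sets use times
up to 5 min and ranges whose size is increased by 25% (high end only), so
every method must extrapolate. Rates are corrupted with zero-mean Gaussian
noise of standard deviation half the long-time rate standard deviation of
each species (`benchmarkSigmaTable`); concentrations are noise-free; the
stored `sigma'` equals the true noise sd. Test rates are noisy by default
— they are "measurements" generated the same way — with a switch for
noise-free truth.

Numerical details of the generator worth knowing:

* `longTimeRateStd` integrates one trajectory, discards a 30-minute
  transient, samples 6000 uniformly spaced states over 30 minutes, trims
  the sample to whole oscillation cycles (first to last S1 maximum) to
  remove partial-cycle phase bias, and takes per-species standard
  deviations of the rates. With these settings the estimate is stable to
  better than 0.1% across initial conditions and sampling resolutions.
  The long transient matters: from initial conditions near the edges of
  the sampling box the approach to the limit cycle can take tens of
  minutes, far longer than from central starting points.
* Dataset generation integrates all `N` initial conditions as one stacked
  ODE system with a vectorized right-hand side — mathematically identical
  to independent integrations (the copies do not interact) but orders of
  magnitude faster in R. Tolerances are `rtol = 1e-8`, `atol = 1e-10`
  (deSolve's `lsoda`).
* All randomness flows through explicit seeds (`withSeed` restores the
  caller's RNG state), so datasets are bit-reproducible.

What the generator does *not* emulate: intrinsic (demographic) noise in
the dynamics, measurement error on concentrations, correlated or
non-Gaussian rate errors, unobserved species, and input perturbations.
Passing tests on these data therefore demonstrate correct and calibrated
behavior of the inference machinery on a hard nonlinear oscillator under
idealized error assumptions — not robustness to the full messiness of real
chemostat data.

A note on the published rate-variability table for this benchmark: the
literature states both that the tabulated per-species column is the
long-time rate standard deviation and that it is the *noise* (half that
standard deviation). Integrating the model settles the question — the
printed values are close to half the converged rate standard deviations
(ratios 1.9–2.2 across species) — so this package treats the column as
the noise scale, which is what `benchmarkSigmaTable` returns. The residual
few-percent scatter between that converged quantity and the printed values
is consistent with the published numbers being finite-sample estimates;
`ssinfer` reports its converged values rather than tuning toward the
table.

# The experiment drivers

`runExperiment` crosses methods (linear baseline, fully connected
S-system, adaptive S-system) with training sizes, horizons and
realizations; within a cell all methods see identical data. Two evaluation
metrics: the mean over species of the Pearson correlation between
predicted and measured test rates, and the mean standardized squared error
(per-species errors divided by the squared noise scale), with medians
taken across realizations. The fully connected baseline is evaluated at
the *raw final* alternation iterate — the plain procedure, whose erratic
behavior at small N is precisely the overfitting signature of an
unselected 112-parameter fit — while the adaptive method evaluates the
selection winner (best iterate, polished). The default N grid is
`{10, 20, 40, 80, 150, 300}` and the default realization count 10;
the package's own test suite runs scaled-down grids (N up to 300, 3–10
realizations per cell, 5 orderings x 5 realizations for the hierarchy
comparison), sizes chosen so the full suite completes in minutes on one
CPU while keeping the Monte-Carlo error of each asserted ordering small.

# Known limitations

* Alternating regression is a heuristic: on data the mask cannot
  represent, it may stall at (or run away from) points far from the
  penalized optimum. The guards and the BFGS refinement make the
  *selection* well-defined, but parameter estimates in rich masks remain
  sloppy — many parameter combinations predict identically, and only the
  stiff combinations are determined. Interpret individual exponents
  accordingly.
* The Laplace score is a local expansion; with multimodal posteriors
  (possible for rich masks at small N) it can misrank candidates. At very
  small sample sizes the evidence criterion prefers strongly reduced
  models whose best attainable fit underfits — parsimony is enforced even
  when a regularized complex fit would generalize slightly better.
* The hierarchy searches 2J+1 nested masks, not the `2^(2J(J+1))` possible
  structures; the result is the best *in the hierarchy*, which is the
  point of the method, not a limitation of the implementation.
* Hidden species, recasting of arbitrary dynamics into S-system form, and
  stochastic kinetics are out of scope.
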