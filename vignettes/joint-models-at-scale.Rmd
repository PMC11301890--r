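---
title: "Joint longitudinal-survival models at scale: methods and design"
author: "bigjoint authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint longitudinal-survival models at scale: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

bigjoint couples two submodels through shared subject-level random
effects.

**Longitudinal submodel.** For subject $i$ with biomarker measurements
$y_{il}$ at times $t_{il}$,
$$y_{il} = \eta_i(t_{il}) + \varepsilon_{il}, \qquad
  \eta_i(t) = x_i(t)^\top\beta + z_i(t)^\top b_i, \qquad
  \varepsilon_{il} \sim N(0, \sigma^2),$$
with $x_i(t) = z_i(t) = (1, t)^\top$ by default (random intercept and
slope).  The random effects $b_i$ are zero-mean with covariance $D$,
either multivariate normal or multivariate Student-$t$ with fixed
degrees of freedom (default 4).  Only the Gaussian/identity-link
longitudinal family is implemented end to end; the family and link
fields of `model_spec()` are a deliberate extension seam, because the
continuous-biomarker case is the one the package's figures of merit are
built around.

**Survival submodel.** The hazard given baseline covariates $w_i$ and
the accrued trajectory is
$$h_i(t) = h_0(t)\,\exp\{\gamma^\top w_i + \alpha\,\eta_i(t)\},$$
the *current value* association: the instantaneous risk moves with the
subject's current (noise-free) biomarker level, scaled by $\alpha$.
Other association structures (slope, cumulative) are declared out of
scope.

**Baseline hazard.** $\log h_0(t)$ is a clamped cubic B-spline with $Q$
interior knots placed at the $q/(Q+1)$ quantiles of the observed event
times (boundary knots at $0$ and the largest observed time).  A clamped
degree-3 basis with $Q$ interior knots has $Q+4$ basis functions that
sum to one everywhere, so a free intercept plus the full basis is rank
deficient; we keep the intercept $\gamma_0^0$ and drop the first basis
function, leaving $Q+3$ free spline coefficients.  Beyond the boundary
knots the evaluation time is clamped, so the log baseline hazard is
constant past the last knot — this deliberately prevents explosive
extrapolation when dynamic predictions run beyond the range of the
fitting data.  The default $Q = 2$ is our choice: with the intercept it
gives six baseline parameters, enough curvature for the hazards the
simulator produces while keeping every chunk's fit well identified; no
principled automatic rule is offered because knot choice trades bias
against variance in a way that is application specific.

## Priors and posterior

Independent zero-mean normal priors (s.d. 10 by default) on $\beta$,
$\gamma$, $\alpha$ and the baseline coefficients; inverse-Wishart
$(q+1, I)$ on $D$; inverse-gamma $(0.01, 0.01)$ on $\sigma^2$.  The
random-effects density $\sum_i \log p(b_i \mid D)$ is accounted in
`log_prior()` rather than the likelihood, keeping the likelihood
conditional on $b_i$ explicit; the sampled object is the unnormalized
kernel `log_posterior()`.

Survival integrals $H_i(t_0, t_1) = \int_{t_0}^{t_1} h_i(s)\,ds$ use
15-node Gauss–Legendre quadrature per interval with no adaptive
subdivision — the standard choice in joint-model software.  Tests
validate it against dense trapezoid integration; note that a single
15-node rule spanning interior knots of the spline is accurate to about
$10^{-5}$ relative rather than machine precision, which is far below
the Monte-Carlo error of anything the integral feeds.

## The sampler

`fit_mcmc()` is a Metropolis-within-Gibbs scheme:

1. every subject's $b_i$ updated by a joint (intercept, slope)
   random-walk Metropolis step against its own conditional — these $n$
   proposals are evaluated vectorized across subjects;
2. $\beta$, $\gamma$, $\alpha$ and the baseline block
   $(\gamma_0^0, \gamma_0^q)$ as separate random-walk blocks against
   the full posterior;
3. $D$ by a conjugate inverse-Wishart draw given $\{b_i\}$; under
   Student-$t$ effects the $b_i$ are scale mixtures of normals with
   per-subject inverse-gamma mixing draws, preserving conjugacy;
4. $\sigma^2$ by a conjugate inverse-gamma draw given residuals.

Proposal scales adapt during burn-in only (Robbins–Monro on batches of
50, targeting acceptance 0.25 for vector blocks and 0.44 for the scalar
$\alpha$), then freeze, preserving detailed balance for the retained
draws.  Defaults are 4000 iterations with 1000 burn-in and no thinning.
All randomness flows through `set.seed()` at entry, so a fixed seed
yields bit-identical draws.  Hamiltonian samplers would mix faster per
iteration but were rejected to keep the package dependency-light and
byte-reproducible.

## Divide and conquer

`fit_big()` partitions the shuffled subject ids into chunks of
`chunk_size` (a trailing chunk smaller than half a chunk is merged into
its predecessor, and a chunk containing no events is merged forward),
fits each chunk independently with seed `master + chunk index`, and
pools.  Two pooling rules are provided:

* **mean_se** (default): pooled mean $= K^{-1}\sum_k m_k$, pooled
  variance $= K^{-2}\sum_k s_k^2$.  For independent chunks this
  reproduces the $1/\sqrt{n}$ scaling of a full-data fit.
* **precision_weighted**: $\hat\theta = (\sum_k H_k)^{-1}\sum_k H_k
  m_k$ with $H_k$ the inverse of chunk $k$'s posterior covariance of
  the scalar parameters, mirroring information-matrix updating.  A
  singular chunk covariance is an error; no silent regularization.

The two rules coincide exactly when chunk covariances are equal and
diagonal.  Knots are placed once from the full event-time set and
shared by all chunks — chunk-specific bases would make the baseline
coefficients non-commensurable and pooling meaningless.  Chunks are
disjoint partitions, not bootstrap resamples, and summaries (not raw
draws) are pooled; draw concatenation is possible future work.

## Dynamic prediction

For a subject with history $\mathcal{H}_i(s)$ (records up to landmark
$s$, known to be event-free at $s$), `posterior_b_given_history()`
samples
$$p(b_i \mid \mathcal{H}_i(s)) \propto p(b_i \mid \hat D)\,
  \prod_{t_{il} \le s} N(y_{il}\mid \eta_i(t_{il}), \hat\sigma^2)\,
  e^{-H_i(0, s)},$$
with population parameters plugged in at their pooled posterior means
(empirical-Bayes style — the pooled fit retains only means and standard
errors, not joint draws, so population-parameter uncertainty is *not*
propagated into the bands; this is a documented limitation).  The
survival-to-landmark factor $e^{-H_i(0,s)}$ is included because the
prediction conditions on $T_i > s$; subjects still alive tend to have
lower trajectories when $\alpha > 0$, and omitting the factor would
bias $b_i$ upward.

Conditional survival is then the Monte-Carlo average of
$S(u \mid s, b) = \exp\{-H_i(s, u \mid b)\}$ over draws, with
equal-tailed 95% pointwise bands; $S(s \mid s) = 1$ holds exactly.
Trajectory predictions report $\eta_i(t)$ per draw the same way.

## Predictive-performance measures

The package fixes the two standard estimators explicitly, and names
them in output metadata:

* **Concordance over time**: at each grid time $t$, Harrell-usable
  pairs truncated at $t$ — $(i,j)$ with $T_i < T_j$, $\delta_i = 1$,
  $T_i \le t$ — scored by whether $\hat S_i(t) < \hat S_j(t)$, ties
  counting one half.  Points with no usable pairs are reported missing.
* **Prediction error over time**: the inverse-probability-of-censoring
  weighted Brier score with Kaplan–Meier censoring weights, $\hat G$
  evaluated left-continuously at event times per the standard IPCW
  convention.  With no censoring all weights are one and the measure
  reduces to the plain mean squared error.

The evaluation grid defaults to the deciles of observed event times.
The Kaplan–Meier estimator itself is computed right-continuously
(product over $t_i \le t$); the strict-inequality variant appears in
some formulations, and every bundled test queries at non-event times
where the two conventions agree.

## The simulator

`simulate_joint_dataset()` draws, per subject: one standard-normal
baseline covariate per element of $\gamma$; random effects from the
configured law; an event time by inverting the subject's cumulative
hazard (bracketed root refinement to $10^{-8}$, with an infinity
sentinel past ten administrative horizons); censoring as the minimum of
an exponential time and the horizon $\tau$; and noisy biomarker values
on a fixed visit grid at visits strictly before the observed time (the
baseline visit always kept).

Deliberate asymmetry: the generator uses a *constant* true log baseline
hazard so that closed-form checks exist, while the fitted model's
spline must recover an approximately flat curve.  Defaults are
$n$-free: $\beta = (0.5, 0.3)$, $D = \mathrm{diag}(0.4, 0.04)$,
$\sigma = 0.3$, $\gamma = 0.4$, $\alpha = 0.6$, $\log h_0 = -0.7$,
$\tau = 3$, visits $0, 0.25, \ldots, 2.75$, censoring rate 0.25
(roughly a quarter of subjects censored — a realistic clinical level).
What the simulator does **not** emulate: informative censoring,
missing-not-at-random visit processes, irregular visit gaps,
measurement batch effects, or time-varying baseline covariates.
Passing recovery tests therefore demonstrate correctness of the
machinery under the model's own assumptions, not robustness to their
violation on real EHR data.

Post-event longitudinal records — routine in EHR extracts — are dropped
with a reported count by `validate_join()` in the default pipeline
(erroring is available via `drop_post_event = FALSE`); the choice to
drop rather than fail is ours and is flagged here because upstream
conventions differ.

## Numerical choices and degenerate inputs

* OLS-based initialization; $D$ diagonal floored at $0.01$, $\sigma$
  floored at $0.01$ for degenerate (constant-outcome) data; baseline
  intercept at the log crude event rate.  Data with zero events abort
  with a clear error.
* If the posterior is non-finite at initialization, the sampler jitters
  up to 100 times before aborting with a diagnostic.
* Sub-seeds for chunks, subjects and pipeline stages are derived
  deterministically from the master seed and stay within 32-bit range.
* Ties in longitudinal record times keep file order; knot placement
  uses the type-7 quantile rule.

## Problem sizes used in the bundled checks

The test suite exercises recovery at $n = 500$ subjects with 4000 MCMC
iterations over 10 replicate seeds, and divide-and-conquer consistency
at $n = 400$ with $K = 4$ chunks against a full-data fit over 10 seeds
— sizes at which the posterior is informative for every parameter while
a full replicate set completes in minutes on a single core.  The
acceptance script runs the full pipeline at $n = 500$ with $K = 4$.
Large-cohort use simply raises `chunk_size` and the chunk count; memory
stays bounded by the largest chunk.

## Known limitations

One longitudinal outcome; Gaussian/identity only; current-value
association only; no competing risks, cure fractions, frailties or
time-varying $\gamma$; no penalized-spline smoothness prior on the
baseline coefficients; population-parameter uncertainty not propagated
into dynamic predictions; in-process sequential chunk fitting (the
chunk loop is embarrassingly parallel, but scheduler integration is out
of scope).
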