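---
title: "Dynamic RMST curves from mixture Weibull models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic RMST curves from mixture Weibull models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynrmst)
```

# The estimand

For a survival time $T$ and a horizon $\tau > 0$, the restricted mean
survival time is
$$\mu(\tau) = E[\min(T, \tau)] = \int_0^\tau S(t)\,dt,$$
the area under the survival curve up to $\tau$ — the $\tau$-window life
expectancy. Its variance over the window is
$$\mathrm{var}(X) = 2\int_0^\tau t\,S(t)\,dt - \mu(\tau)^2,$$
whose square root is the restricted standard deviation (`rmst_var()`).
In a two-arm trial with survival $S_0$ (control) and $S_1$ (treatment) the
effect measures are the difference $\Delta(\tau) = \mu_1(\tau) -
\mu_0(\tau)$ (the area between the curves), the ratio $\theta(\tau) =
\mu_1(\tau)/\mu_0(\tau)$, and — useful when events are rare and $\theta$
crowds 1 — the ratio of restricted mean time lost, $(\tau - \mu_1)/(\tau -
\mu_0)$. None of these requires proportional hazards, which is the point:
delayed effects, crossing curves and cure-like plateaus all leave RMST
well-defined and interpretable.

A *dynamic* RMST analysis evaluates these contrasts over a whole grid of
horizons rather than a single pre-specified $\tau$, tracing the evolution of
the treatment effect. Read at a glance: a difference curve hugging zero
early and rising late is a delayed effect; a sign change is a crossing; a
flattening ratio suggests the follow-up has captured the attainable effect.

# The parametric model

Each arm is modelled independently as a finite mixture of Weibull
components,
$$S(t) = \sum_{j=1}^{J} p_j \exp\!\left[-\left(t/\lambda_j\right)^{k_j}\right],
\qquad J \le 3,$$
with weights $p_j > 0$, $\sum_j p_j = 1$, scales $\lambda_j > 0$ (time
units) and shapes $k_j > 0$. One component is an ordinary Weibull
(exponential at $k = 1$); two or three well-separated components reproduce
the non-proportional shapes above. A cure-like plateau is represented by a
component whose scale far exceeds the follow-up horizon — there is no
explicit point-mass cure fraction, which keeps the likelihood smooth at the
cost of a weakly identified plateau scale (see *Numerical safeguards*).

The likelihood for right-censored data $(t_i, \delta_i)$ is the standard
censored-data form $\sum_i [\delta_i \log f(t_i) + (1 - \delta_i) \log
S(t_i)]$, accumulated with log-sum-exp across components. Subjects censored
at $t = 0$ contribute $\log S(0) = 0$ and are harmless; an *event* at
exactly $t = 0$ makes the Weibull likelihood zero or unbounded and is
rejected.

## Closed-form restricted moments

With the lower incomplete gamma function $\gamma(s, x) = \int_0^x t^{s-1}
e^{-t} dt$,
$$\int_0^\tau e^{-(t/\lambda)^k} dt = \frac{\lambda}{k}\,
\gamma\!\left(\tfrac1k, (\tau/\lambda)^k\right), \qquad
\int_0^\tau t\, e^{-(t/\lambda)^k} dt = \frac{\lambda^2}{k}\,
\gamma\!\left(\tfrac2k, (\tau/\lambda)^k\right),$$
so $\mu(\tau)$ and the restricted variance are weighted sums of
incomplete-gamma terms (`weibull_rmoment()`), valid at *any* horizon —
including beyond follow-up, which is what the Kaplan–Meier estimator cannot
do. As $\tau \to \infty$ they converge to $(\lambda/k)\Gamma(1/k)$ and
$(\lambda^2/k)\Gamma(2/k)$. We evaluate $\gamma(s,x)$ as the regularized
incomplete gamma (`pgamma`) times $\Gamma(s)$ on the log scale; this stays
finite for small shapes, where $s = 1/k$ is large and $\Gamma(s)$ alone
would overflow. The test suite checks these closed forms against adaptive
quadrature of $S(t)$ and $t\,S(t)$ over hundreds of random configurations.

# Fitting

## Parameterization

Optimization runs on an unconstrained transform: $\log \lambda_j$, $\log
k_j$, and multinomial logits of the weights with the last component as
reference. All inference (covariance, delta-method gradients) lives on this
scale, which respects the positivity and simplex constraints without
boundary handling.

## Starting values and multi-start

Mixture likelihoods are multimodal, so `weibmix_fit()` runs a multi-start
scheme (default `n_starts = 10`). The first start is a quantile-split
heuristic: the sorted observed times are cut into $J$ contiguous blocks,
each block mean seeds one scale, shapes start at 1, weights equal. The
remaining starts jitter this vector with seeded Gaussian noise (sd 0.5 on
the transformed scale). The heuristic is deliberately simple and
reproducible; given the seed, the entire fit is deterministic, and the data
are internally sorted so the result is invariant to row order.

## Optimizer

Each start runs L-BFGS-B with the *analytic* gradient of the censored
log-likelihood (validated against central differences in the tests), a
relative function-convergence tolerance of $10^{-9}$, and at most 500
iterations. Computing likelihood and score in one cached pass roughly
halves the cost per iteration at the sample sizes the simulations use. Box
bounds implement numerical guardrails rather than scientific constraints:
shapes in $[0.01, 100]$, log-scales within $\pm 10$ of the observed time
range, weight logits capped at $\pm 13.8$ (a $10^{-6}$ weight floor). A
weight that collapses to the floor triggers a warning recommending fewer
components. Exponents $(t/\lambda)^k$ are capped at $e^{700}$ so extreme
proposals degrade gracefully instead of producing NaNs.

## Covariance

The parameter covariance is the inverse of the observed information —
central finite differences of the analytic score (step $10^{-4}$ on the
transformed scale), symmetrized. A resampling scheme would be the obvious
alternative; observed information was chosen because it is deterministic,
cheap, and exposes ill-conditioning directly. If the information matrix has
condition number above $10^{10}$ the package warns and uses a
pseudo-inverse (dropping non-positive eigendirections); if it is outright
singular the model is returned with the covariance flagged unavailable and
all inference disabled rather than silently wrong. Before reporting, the
components are relabelled in increasing scale order — the likelihood is
invariant under permutation, so this only fixes a canonical
representative.

## Choosing the number of components

Three components are the default, matching the flexibility argument behind
the model; one or two are supported, and `select_components()` offers
opt-in AIC/BIC selection when no subject-matter knowledge pins $J$ down.
Automatic selection is *not* the default because domain knowledge about the
study population, where available, should override an information
criterion.

# Inference

The standard error of $\mu(\tau)$ comes from the delta method: the
gradient of $\mu(\tau;\Theta)$ with respect to the transformed parameters
(central differences, relative step $10^{-5}$) against the
observed-information covariance. Hand-derived incomplete-gamma parameter
derivatives would be possible but error-prone; the finite-difference
gradient is validated by the quadrature cross-checks and coverage
simulations. Confidence intervals for $\mu(\tau)$ are truncated to $[0,
\tau]$, the parameter space of an RMST.

Arms are independent, so $\mathrm{var}(\Delta) = \mathrm{var}(\mu_1) +
\mathrm{var}(\mu_0)$ with a normal interval. Ratio-type contrasts are
handled on the log scale — $\mathrm{var}(\log\theta) =
\mathrm{var}(\mu_1)/\mu_1^2 + \mathrm{var}(\mu_0)/\mu_0^2$ — and
exponentiated, which keeps the interval positive; the same treatment
applies to the RMTL ratio with $\tau - \mu$ in place of $\mu$. Contrast
intervals are left untruncated to avoid distorting between-arm inference.
All p-values are two-sided normal; where reported sidedness conventions are
ambiguous in the literature this package is explicit: two-sided,
$2\Phi(-|z|)$.

# The Kaplan–Meier reference engine

`km_fit()` computes the product-limit estimator by direct counting, with
the universal convention that deaths precede censorings at tied times.
`rmst(km, tau)` integrates the step function exactly and uses the
Greenwood-type variance
$$\widehat{\mathrm{var}} = \sum_{t_i \le \tau} A_i^2\,
\frac{d_i}{n_i (n_i - d_i)},$$
where $A_i$ is the area under $\hat S$ from $t_i$ to $\tau$. When the last
subject at risk dies ($n_i = d_i$) the term is undefined; it is dropped
with a warning, matching the convention of the widely used KM-RMST
implementations. The KM engine refuses horizons beyond the largest observed
time — the estimator simply does not exist there — with an error that
points at the parametric engine. Within follow-up, `km_mixture_agreement()`
summarizes the discrepancy between the engines in absolute units and in
KM standard errors; a smooth model that fits will sit within about two KM
standard errors everywhere, and the acceptance tests hold the simulator to
exactly that at 5000 subjects per arm.

# The dynamic curve

`dynrmst()` fits both arms, computes the default horizon as the minimum
over arms of the largest observed (event *or* censored) time — the same
convention that makes the default $\tau$ of KM-based RMST software
data-dependent — and evaluates both engines over a grid. Defaults and
policies:

* **Grid**: 100 equally spaced points from $\tau_d/100$ to the default
  $\tau_d$. The computation is pointwise, so refining the grid changes
  nothing at shared horizons (tested).
* **Extrapolation**: the parametric curve extends beyond follow-up, but the
  grid is clamped (with a warning) at `extrapolation_factor` (default 1.5)
  times $\tau_d$. Extrapolation far beyond the data answers a question the
  data cannot check; 1.5 is a deliberate, conservative default, not an
  estimate.
* **Ties at the default horizon**: if the two arms' maxima tie, the default
  $\tau$ is their exact common value.
* **KM rows** are *absent*, not zero, at horizons beyond an arm's
  follow-up; contrasts under the KM engine require both arms defined.
* **Plateau reporting** (`follow_up_adequacy()`): the relative change of
  each contrast over the trailing 20% of the grid, flagged against a 1%
  threshold, plus the grid horizon nearest a ratio crossing of 1. These are
  descriptive diagnostics, not tests — the thresholds are configuration,
  and no changepoint inference is attempted.

# The trial simulator

`trial_scenario()`/`simulate_trial()` emulate a randomized two-arm trial:
uniform accrual over 12 time units, total study duration 36 (administrative
censoring at duration minus entry, on the study-time scale), exponential
dropout at rate 0.01, 300 subjects per arm unless overridden. Latent event
times come from per-arm mixture Weibull truths; four presets give the
canonical hazard shapes:

| preset | control | treatment | shape |
|---|---|---|---|
| `ph` | Weibull(10, 1) | Weibull(14, 1) | constant hazard ratio 10/14 |
| `delayed` | Weibull(8, 1) | 0.5·W(3.8, 1) + 0.5·W(25, 2.5) | arms separate late |
| `crossing` | Weibull(10, 1) | 0.5·W(3, 0.5) + 0.5·W(30, 3) | treatment worse early, better late |
| `cure` | Weibull(8, 1) | 0.75·W(8, 1) + 0.25·W(10⁴, 1) | 25% plateau |

The preset numerics are engineered constants, chosen once so that each
scenario exhibits its shape *quantitatively*: the delayed treatment's early
component ($\lambda = 3.8$) approximately matches the control hazard near
$t = 0$, so the true $\Delta(3)$ is below 0.05 time units while
$\Delta(30)$ exceeds 4 (verified in closed form by `true_rmst_curve()`);
the crossing survival curves intersect near $t = 4.5$; the cure plateau
keeps $S_1(100) \approx 0.25$. A naive "delayed" mixture whose late
component simply has low early hazard would make the treatment better from
$t = 0$ — matching the early hazards is what makes the delay real.

What the simulator does *not* emulate: covariate-driven heterogeneity,
non-uniform accrual, informative censoring, interval censoring, competing
risks. Passing the simulation suite therefore shows the estimator and its
inference are correct *under the model and an independent-censoring trial
design* — it cannot certify behaviour under informative dropout or model
misspecification beyond what the KM-agreement checks reveal.

# What the tests establish, and at what scale

The statistical acceptance suite (all seeded, all computed at test time)
checks:

* closed forms against adaptive quadrature (200 random configurations,
  $10^{-8}$);
* exponential analytic identities to $10^{-12}$;
* the exact no-censoring identity of KM-RMST with the sample mean of
  $\min(t_i, \tau)$ (100 random datasets);
* parameter/function recovery on all four presets at 2000 subjects per arm,
  10 replicates each: fitted survival within 0.03 of truth in sup-norm on
  $[0, \tau_d]$ on average, and $\mu(\tau_d)$ within 3 standard errors of
  truth in at least 90% of fits;
* 95% CI coverage for $\Delta(18)$ in $[0.92, 0.975]$ over 500 replicates
  of a two-component scenario at 300 subjects per arm, and two-sided size
  within 3 binomial standard errors of 5% under identical arms (500
  replicates);
* KM–mixture agreement within 2 KM standard errors everywhere on the grid
  at 5000 subjects per arm;
* structural invariants: arm-swap antisymmetry of $\Delta$ and inversion of
  $\theta$, monotone and 1-Lipschitz $\mu(\tau) \le \tau$, ratio and RMTL
  ratio crossing 1 exactly where $\Delta$ crosses 0, label-switching
  invariance, and end-to-end determinism under fixed seeds.

The replicate counts and sample sizes above are the package's chosen
simulation scale: large enough that the binomial noise of a coverage
estimate is small against the acceptance bands, small enough to run
routinely. The simulation-heavy checks use 4–5 multi-starts per fit rather
than the default 10; the multimodality risk at these sample sizes is
modest and the quantile-split start is already close.

# Known limitations

* No covariate adjustment: the mixture is fitted per arm without
  regression structure.
* No simultaneous (uniform-in-$\tau$) confidence bands; all intervals are
  pointwise, so the dynamic curve should be read as a profile, not as a
  joint test.
* Cure behaviour is a long-scale component, not a point mass; its scale is
  weakly identified and the covariance machinery will warn accordingly.
  RMST itself remains well-estimated because it depends on $S$ only through
  the window.
* The delta method is first-order; at small samples (tens of subjects per
  arm) its intervals can undercover, and the KM engine is the safer
  reference there.
* Ratio contrasts are undefined when the denominator RMST (or RMTL) is
  zero; the package raises errors rather than returning infinities.
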