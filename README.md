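# dynrmst

Dynamic restricted mean survival time (RMST) curves for two-arm survival
trials, built on parametric mixture-of-Weibull survival models.

## Why

Immuno-oncology trials routinely violate proportional hazards: delayed
treatment effects, crossing survival curves, and cure-like plateaus all break
the single-hazard-ratio summary, and the log-rank test loses power. RMST —
the mean of min(T, τ), equivalently the area under the survival curve up to a
horizon τ — is a model-free, clinically interpretable alternative: the
τ-window life expectancy. Its drawback, when estimated by integrating the
Kaplan–Meier curve, is that it cannot be evaluated beyond follow-up and is
noisy near the tail.

`dynrmst` instead models each arm's survival as a finite mixture of Weibull
components,

S(t) = Σⱼ pⱼ exp[ −(t/λⱼ)^kⱼ ],  j = 1…J ≤ 3,

fitted to right-censored data by maximum likelihood. RMST then has a closed
form at any horizon via the lower incomplete gamma function
γ(s, x) = ∫₀ˣ t^(s−1) e^(−t) dt:

∫₀^τ exp[−(t/λ)^k] dt = (λ/k) · γ(1/k, (τ/λ)^k),

so the treatment effect can be traced as a **dynamic curve**: the RMST
difference Δ(τ) = μ₁(τ) − μ₀(τ) and ratio θ(τ) = μ₁(τ)/μ₀(τ) over a grid of
horizons, with pointwise confidence intervals from the delta method on the
observed-information covariance. A Kaplan–Meier RMST engine (Greenwood-type
variance) provides the nonparametric reference inside follow-up, and the two
engines are compared automatically.

The package also ships a seeded two-arm trial simulator (uniform accrual,
administrative censoring, exponential dropout) with presets for
proportional-hazards, delayed-effect, crossing-hazards and cure-fraction
shapes, so every estimator and inference path is testable without external
data.

## Worked example

```r
library(dynrmst)

sc  <- trial_scenario("delayed", n = 300, seed = 101)  # delayed-effect truth
ds  <- simulate_trial(sc)
fit <- dynrmst(ds, n_components = c(1, 2), seed = 101, n_starts = 5)
print(fit)
```

```
Dynamic RMST analysis (mixture Weibull vs Kaplan-Meier)
  arms: control 'control' vs treatment 'treatment'; n = 600; default tau = 32.0045
  RMST at default tau: treatment 11.938, control 7.333 (mixture engine)
RMST difference (trt - ctrl) (mixture engine) at tau = 32.0045: 4.6045  95% CI [3.0452, 6.1638]  p = 7.143e-09
RMST ratio (trt / ctrl) (mixture engine) at tau = 32.0045: 1.6279  95% CI [1.3883, 1.9088]  p = 1.984e-09
```

The default horizon is the minimum over arms of the largest observed time
(32.0 here). Within the 32-unit window a treated subject survives 11.94 time
units on average against 7.33 under control: 4.60 units gained, a 63%
increase in window life expectancy, both intervals excluding the null.

```r
km_mixture_agreement(fit)   # parametric vs KM RMST over the shared grid
```

```
        arm n_shared    max_abs   mean_abs max_se_units
1   control      100 0.10702142 0.05172511    0.2993917
2 treatment      100 0.02619062 0.00703950    0.5422274
```

The smooth parametric curve stays well within one KM standard error of the
nonparametric estimate everywhere on the grid.

```r
follow_up_adequacy(fit)
```

```
Follow-up adequacy (trailing 20% of grid, threshold 0.01):
  difference: relative change 0.1729 -> plateau: no
  ratio: relative change 0.05253 -> plateau: no
```

Neither contrast has plateaued by the end of follow-up — longer follow-up
would still sharpen the effect estimate, exactly the pattern expected under a
delayed effect. `plot(fit)` draws the Δ(τ) and θ(τ) panels with CI ribbons
and both engines overlaid; `export_curve(fit, "curve.csv")` writes the tidy
per-horizon table.

A command-line interface wrapping the same functions is installed at
`inst/cli/dynrmst.R` with subcommands `simulate`, `fit`, `curve` and `km`.

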