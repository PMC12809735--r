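# hdmixed

Environment-sensitive height-diameter (H-D) models for mixed forests.

Forest inventories measure every tree's diameter at breast height (D, cm) but
only a subsample of heights (H, m), so H-D models are fitted constantly. In
mixed, uneven-aged stands one curve does not fit all: the H-D relationship
shifts with stand development, competition, species diversity, climate and
soil. `hdmixed` implements the full modelling pipeline for this situation:

* **Base model** — the power law `H = 1.3 + β₀ D^β₁` (1.3 m is breast
  height; β₁ is the allometric scaling exponent, ≈ 2/3 under
  metabolic-scaling theory).
* **Covariate-extended model** — covariates act on the exponent:
  `H = 1.3 + β₀ D^(β₁ + β₂·SOC + β₃·MAP + β₄·SIM + β₅·BAL + β₆·QMD)`,
  with soil organic carbon (g/kg), mean annual precipitation (mm), the
  Gini-Simpson diversity index, the basal area of larger trees (m²/ha) and
  the quadratic mean diameter (cm).
* **Two-level nonlinear mixed-effects model** — plot-level random effects on
  (β₀, β₁) and a species-within-plot effect on the QMD coefficient,
  estimated by maximum likelihood with a Lindstrom-Bates-style alternating
  algorithm (penalized nonlinear least squares + a linearized
  mixed-model step), with heteroscedastic variance functions of diameter
  (exponential, constant-plus-power, power) and likelihood-ratio comparison.
* **Covariate machinery** — stand metrics (QMD, BAL, basal area, dominant
  height), diversity indices (Simpson, Shannon), site composites
  (SIE/CIE Stage transforms), climate composites (de Martonne M, annual
  heat:moisture), two-stage selection with VIF ≤ 5 screening and a nested
  AIC ladder.
* **Evaluation and analysis** — R², RMSE, signed total relative error,
  refit-based partial R², per-species scaling exponents vs 2/3,
  covariate-gradient curves at the 5th/50th/95th percentiles, and marginal
  covariate slopes.
* **Synthetic-forest generator** — hierarchical forests with the survey's
  marginal structure (99 plots, ~7,800 trees, five species) and the full
  random-effect error model, for parameter-recovery studies and testing.

## Worked example

```r
library(hdmixed)

# a synthetic mixed forest at the study scale (seed-deterministic)
syn <- make_fixture("survey_scale", seed = 20260925)
frame <- syn$frame                      # trees + plot covariates + QMD/SIM/BAL

spec <- hd_model_spec(c("SOC", "MAP", "SIM", "BAL", "QMD"))
fit <- fit_hd_nlme(frame, spec,
                   hd_re_spec(plot = c("beta0", "beta1"), species = "QMD"))
print(fit)
```

```
hd_nlme fit: n = 7923, 99 plot(s); logLik -16080.40, AIC 32184.8
        estimate        se          p
beta0  1.7410000 7.382e-02 6.316e-123
beta1  0.4964000 2.127e-01  1.962e-02
SOC   -0.0011600 3.862e-04  2.679e-03
MAP    0.0008898 4.287e-04  3.794e-02
SIM    0.0946000 5.129e-02  6.511e-02
BAL    0.0021510 5.938e-05 2.831e-287
QMD   -0.0023950 4.176e-03  5.662e-01
plot-level SDs: beta0 0.6775, beta1 0.09943
species-level SD: 0.001801
sigma 1.7174, variance function: none
```

The generator's truth is β₀ = 1.784, β₁ = 0.823, plot SDs 0.736 and 0.110,
species SD 1.6e-3, σ = 1.73: the variance components and σ are recovered
closely, and β₀, β₁ and the covariate coefficients land within a few of
their (large, ridge-correlated) standard errors — with a strong plot-level
random exponent,
β₀ and β₁ trade off along a likelihood ridge while the fitted height curve
itself stays close to the truth (see the vignette). Evaluating the three
model tiers on the same forest:

```r
hd_evaluate(fit)          # conditional predictions
aic_ladder(hd_model_frame(syn$dataset))
```

| model | AIC | R² | RMSE (m) | TRE (%) |
|-------|-----|----|----------|---------|
| base power (NLS) | 61767 | 0.138 | 11.93 | -0.12 |
| covariate model (NLS) | 60905 | 0.228 | 11.29 | 0.04 |
| mixed model (conditional) | 32185 | 0.983 | 1.69 | 0.02 |

The AIC ladder falls monotonically as QMD, BAL, SIM, MAP and SOC enter the
exponent (61086 → 60246 on the modelling subset), and the mixed model's
standardized residuals have SD ≈ 0.96-1.01 within every species. The
marginal (fixed-effects-only) R² is low by design: the generator's
plot-level random-effect SDs, taken from the reported magnitudes, put most
height variance between plots; the conditional fit recovers it.

The numbered scripts under `analysis/` run the complete workflow —
simulation, ingestion and validation, stand metrics, two-stage selection,
model fitting and variance-function comparison, and the exponent/gradient
analyses — writing all tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_stand_metrics.R
Rscript analysis/03_selection.R
Rscript analysis/04_fit_models.R
Rscript analysis/05_gradient_analysis.R
```

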