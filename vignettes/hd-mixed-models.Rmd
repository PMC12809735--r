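---
title: "Environment-sensitive height-diameter models for mixed forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Environment-sensitive height-diameter models for mixed forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tree height H and diameter at breast height D (measured 1.3 m above ground)
are the two workhorse measurements of forest inventories. Height is slow and
expensive to measure, so height-diameter (H-D) models that predict H from D
are fitted routinely and used for volume, biomass and carbon estimation. In
mixed, uneven-aged forests a single H-D curve is a poor description: the
relationship varies with stand development, competition, species composition,
climate and soil. `hdmixed` implements a complete pipeline for building,
selecting and analysing environment-sensitive H-D models for such forests:

* covariate engineering (stand, site, soil, climate, diversity metrics),
* two-stage covariate selection with variance-inflation screening,
* nonlinear least-squares and two-level nonlinear mixed-effects estimation
  with heteroscedastic variance functions,
* goodness-of-fit and partial-R^2 evaluation,
* allometric-exponent and covariate-gradient analyses, and
* a hierarchical synthetic-forest generator so that every stage is testable
  end to end without field data.

## The models

The base model is the two-parameter power law

$$H_{ijk} = 1.3 + \beta_0 D_{ijk}^{\beta_1} + \xi_{ijk},$$

with plot $i$, species $j$, tree $k$. $\beta_0$ is a scaling coefficient and
$\beta_1$ the allometric scaling exponent; metabolic-scaling theory predicts
$\beta_1 \approx 2/3$, and deviations diagnose environmental or
species-strategy modulation. Covariates act on the exponent:

$$H_{ijk} = 1.3 + \beta_0
  D_{ijk}^{\,\beta_1 + \beta_2\mathrm{SOC}_i + \beta_3\mathrm{MAP}_i +
  \beta_4\mathrm{SIM}_i + \beta_5\mathrm{BAL}_{ijk} + \beta_6\mathrm{QMD}_i}
  + \xi_{ijk},$$

where SOC is soil organic carbon (g/kg), MAP mean annual precipitation (mm),
SIM the Gini-Simpson diversity index, BAL the basal area of larger trees
(m^2/ha, a one-sided competition index) and QMD the quadratic mean diameter
(cm, a stand developmental-stage indicator). The mixed-effects version adds
plot-level effects $\mu_{i1}, \mu_{i2}$ on $\beta_0$ and $\beta_1$ and a
species-within-plot effect $\mu_{ij1}$ on the QMD coefficient:

$$H_{ijk} = 1.3 + (\beta_0 + \mu_{i1})
  D_{ijk}^{\,\beta_1 + \mu_{i2} + \cdots + (\beta_6 + \mu_{ij1})\mathrm{QMD}_i}
  + \xi_{ijk}.$$

Within-plot errors are independent Gaussian with covariance
$\sigma^2 G_i$, $G_i$ diagonal from one of three variance functions of
diameter (within-plot correlation is fixed to the identity; the interface
leaves room for correlation structures but none is implemented, since only
variance functions are exercised by the analysis):

* exponential: $\mathrm{SD} = \sigma e^{\gamma D}$,
* constant-plus-power: $\mathrm{SD} = \sigma\,|\gamma_1 + D^{\gamma_2}|$,
* power: $\mathrm{SD} = \sigma D^{\gamma}$.

## Estimation

`fit_hd_nls()` is a damped Gauss-Newton (Levenberg-Marquardt) minimizer with
the analytic Jacobian of the power model. Covariates are z-scaled internally
(raw magnitudes such as MAP $\approx$ 450 make the exponent surface
ill-conditioned) and estimates, covariance and standard errors are
back-transformed exactly. Convergence requires a relative SSE change below
1e-10 or a gradient max-norm below 1e-8, with at most 200 accepted
iterations; accepted steps never increase the objective. The Gaussian
log-likelihood uses the ML variance $\hat\sigma^2 = \mathrm{SSE}/n$ so that
AIC values are comparable with the mixed-effects fits; standard errors use
the conventional $\mathrm{SSE}/(n-p)$.

`fit_hd_nlme()` maximizes the first-order (linearized) marginal likelihood by
an alternating algorithm in the Lindstrom-Bates tradition:

1. a penalized nonlinear least-squares step updates the fixed effects and the
   random-effect modes at the current variance parameters (per-plot
   Gauss-Newton with step halving on the penalized objective);
2. a linear mixed-effects step linearizes the model about the modes and
   maximizes the profiled marginal likelihood of the working response over
   the variance-covariance parameters (log-Cholesky parameterization of the
   plot-level covariance, log-SD for the species level, raw variance-function
   parameters), with the fixed effects and residual scale profiled out in
   closed form via the Woodbury identity.

Estimation is ML, not REML. The outer loop stops when the marginal
log-likelihood changes by less than `tol` (default 1e-4, at most 20 outer
iterations). AIC/BIC use an explicit parameter census: fixed effects +
plot-covariance parameters + species variance + variance-function parameters
+ $\sigma$; the census is stored on the fit (`k_census`) so the bookkeeping
is auditable. A random-effect SD collapsing below 1e-4 of $\sigma$ is
reported in the fit's `boundary` field.

`hd_marginal_loglik()` evaluates the same first-order marginal likelihood at
user-supplied parameter values (modes found by penalized least squares with
the fixed effects held fixed). With all random-effect variances zero it
reduces exactly to the Gaussian NLS log-likelihood. For random effects on
$\beta_0$, which enter the model linearly, the linearized likelihood equals
the exact integral; this is verified against dense numerical quadrature in
the tests.

### Accuracy of the first-order likelihood

For random effects in the exponent the linearization is genuinely
approximate: the dropped residual-curvature term makes the likelihood deviate
from the exact integral by roughly 1e-3 to 1e-2 (log-likelihood units) at
exponent-level SDs of 0.01-0.1 on small plots. This is a property of the
algorithm, not of this implementation — `nlme::nlme` produces the same
estimates and likelihood values to four or more significant figures, which is
asserted in the test suite. Two practical consequences documented by the
recovery simulations:

* $\hat\beta_0$ and $\hat\beta_1$ trade off along a likelihood ridge when
  the exponent carries a sizeable plot-level random SD, so their medians can
  sit a few percent off the simulation truth in opposite directions while
  the fitted population height curve stays within a few percent of the true
  curve; recovery is therefore assessed on the curve.
* tree-level exponent coefficients (the BAL coefficient in particular) can
  carry a bias of order 10-15% of their small magnitudes under strong
  exponent-level heterogeneity; the identical values arise from `nlme`.

## Covariate selection

Stage 1 fits the base model per species (species with fewer than
`min_species_n = 100` trees are excluded, reproducing the survey's
"insufficient data" rule) and computes Pearson correlations, with two-sided
t-test p-values, between the species coefficients and candidate covariates;
constant covariates are reported as undefined rather than dropped silently.
Stage 2 screens candidates by the variance inflation factor
$\mathrm{VIF}_j = 1/(1-R_j^2)$, iteratively removing the worst covariate
until all VIF $\le 5$ (ties break lexicographically; exact collinearity is
dropped immediately). Tree-level BAL is averaged to plot level for the
collinearity screen, since VIF mixes scales otherwise. `aic_ladder()` then
fits the nested model sequence (base, +QMD, +BAL, +SIM, +MAP, +SOC by
default) and reports AIC, log-likelihood and R^2 per rung.

## Evaluation

$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$, $\mathrm{RMSE} =
\sqrt{\mathrm{SSE}/n}$ (m) and the signed total relative error
$\mathrm{TRE} = 100\sum(H^O - H^E)/\sum H^E$ (%) are computed overall and per
species; mixed fits are evaluated with conditional
(random-effects-included) predictions by default, with a population-level
option. Partial R^2 is the refit difference $R^2_{\mathrm{full}} -
R^2_{\mathrm{reduced}}$, recomputed by dropping one covariate at a time; for
the diameter term the reduced model drops the power term entirely (a
constant-height model with $R^2 = 0$), so the partial R^2 of D equals the
full-model R^2. Single-covariate drops need not sum to any total — the
decomposition ranks, it does not partition.

## Gradient and exponent analyses

`species_exponents()` compares per-species exponents (and the pooled
cross-species exponent) against 2/3 via Wald intervals.
`gradient_simulation()` traces the population-level (random effects at zero)
height response over a diameter grid with the target covariate at its
empirical 5th/50th/95th percentiles (linear-interpolation quantiles) and all
other covariates at their means. Percentiles and means are computed per
species from each species' own covariate distribution — with random effects
at zero the fixed-effect curve is otherwise species-invariant, and species do
occupy different environments, so this is what makes the per-species panels
informative. `slope_summary()` reports finite-difference sensitivities
$\partial \hat H/\partial x$ at covariate means and median diameter, step 1%
of the covariate SD; the analytic derivative
$\beta_0 D^e \ln D\, \beta_x$ is recovered to 1e-6 relative in tests.

## The synthetic-forest generator

`sim_config()` + `simulate_heights()` generate hierarchical forests with the
structure the models assume, at the scale of a 99-plot, five-species,
~7,800-tree temperate mixed-forest survey:

* plot areas 0.06/0.10/0.25 ha in a fixed 93/5/1 composition (the survey's
  implied mean plot area is about 0.065 ha) and stem densities from a
  truncated normal (1197 ± 486, range 290-2667 stems/ha);
* per-plot species richness (probabilities 0.35/0.30/0.20/0.10/0.05 for 1-5
  species) and within-plot composition from a symmetric Dirichlet
  (concentration 0.5), calibrated so that the Simpson-index marginal spans
  0-0.7 with mean near 0.2, including pure plots;
* per-species diameters from truncated normals on [5 cm, species maximum]
  with the reported species means and SDs (a Weibull alternative is
  available);
* plot covariates (SOC, MAP, MAT, elevation, slope) from truncated normals
  with the reported means, SDs and ranges, drawn independently across plots
  and of each other;
* QMD, SIM and per-tree BAL computed from the realized tree lists — never
  sampled — because the model couples tree diameters to stand covariates and
  independent sampling would destroy exactly the structure the mixed model
  exploits;
* heights from the full hierarchical model with fixed effects
  (1.784, 0.823, -1e-3, 2e-4, 0.1044, 2e-3, -5e-3), plot-level SDs
  (0.736, 0.110) on $(\beta_0, \beta_1)$, species-level SD 1.6e-3 on the QMD
  coefficient, and residual scale 1.73 m, the magnitudes reported for
  larch-birch mixed forests. Gaussian noise can place a height below breast
  height; such heights are redrawn up to 10 times and then clipped to 1.31 m
  with a logged count (a handful of trees per ~8,000).

A single integer seed drives named substreams (plots, trees, effects, noise),
so changing the number of trees does not perturb the plot covariates.

What the generator does **not** emulate — and hence what passing tests do not
establish about field data: spatial structure and spatial autocorrelation;
correlations among plot covariates (real MAP and elevation are correlated);
diameter measurement error; remeasurement of permanent plots; mortality and
growth. Marginal (fixed-effects-only) R^2 on synthetic data is much lower
than values reported from field stands, because the reported plot-level
random-effect SDs are large relative to the fixed effects; conditional R^2
is comparable.

## Numerical choices and edge cases

* BAL uses strictly greater diameters; equal-diameter trees contribute
  nothing to each other, making the BAL of the unique largest tree exactly 0.
* The Simpson index is the Gini-Simpson form $1 - \sum p_i^2$, so pure
  stands score 0 (the raw form $\sum p_i^2$ would score 1).
* Slope is recorded in degrees and converted to radians before the Stage
  transforms $\mathrm{SIE} = \sin(\mathrm{SL})\ln(\mathrm{EL})$,
  $\mathrm{CIE} = \cos(\mathrm{SL})\ln(\mathrm{EL})$.
* Heights at or below 1.3 m are flagged on reading and excluded from fitting
  with a message (the model is undefined below breast height); diameters
  below the 5 cm survey threshold are excluded from the modelling subset
  (configurable).
* The fixed-effects simulation truth uses a negative SOC coefficient
  (-6.07e-4 in the covariate-model recovery study), consistent with the
  negative mixed-model coefficient and with the inhibitory effect of soil
  organic carbon on height growth these forests show.
* The variance-function identification study in the acceptance suite uses a
  constant-plus-power truth with a negative offset ($\gamma_1 = -2.5$,
  $\gamma_2 = 0.6$), which places the SD minimum near the survey threshold.
  With positive offsets of plausible magnitude, $\log(\gamma_1 + D^{\gamma_2})$
  is numerically linear in $\log D$ over a 5-60 cm diameter range, so the
  constant-plus-power and power families are indistinguishable at any sample
  size and no selection procedure could recover the generating family; the
  negative-offset regime is where the family is genuinely identifiable.

## Problem sizes in the test and acceptance suites

The recovery studies run at sizes chosen to estimate each quantity with
adequate precision: base- and covariate-model recovery at the full survey
scale (~7,800 trees, 20 replicates); mixed-model recovery at 60 plots x 40
trees, 20 replicates; oracle equivalence on 25 instances of at most 12
observations; variance-function identification at 25 plots x 20 trees (20
replicates) and null LRT calibration at 15 plots x 12 trees (200
replicates).

## Known limitations

* The marginal likelihood is the first-order Lindstrom-Bates approximation;
  no adaptive quadrature or REML option is provided.
* No within-plot error correlation structures, no crossed random effects,
  and no EBLUP calibration for predicting heights in new plots (prediction
  for new plots is population-level only).
* The generator draws plot covariates independently; an inter-covariate
  correlation structure would be needed to study confounded selection.
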