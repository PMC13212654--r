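---
title: "Modelling oxygen consumption of farmed Atlantic salmon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxygen consumption of farmed Atlantic salmon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmonMO2)
```

## The model

Dissolved oxygen is the binding constraint of modern salmon farming, and
simulations of cage oxygen dynamics stand or fall with the quality of their
oxygen-demand term. `salmonMO2` implements a fundamental model for the
mass-specific oxygen consumption rate of seawater-adapted Atlantic salmon
post-smolts,

$$\mathrm{MO}_2 = a\,W^{b}\,c^{T}\,d^{U},$$

where $\mathrm{MO}_2$ is in mg O~2~ kg^-1^ h^-1^, $W$ is body weight (kg),
$T$ is water temperature (°C) and $U$ is relative swimming speed (body
lengths s^-1^). The three components have physiological backing: allometric
mass scaling ($W^b$, with $b < 0$ for mass-specific rates), an exponential
temperature dependence ($c^T$, a discretised Arrhenius-type response), and an
exponential swimming-cost term ($d^U$). Exponential forms for $T$ and $U$ are
empirically indistinguishable from the mechanistic alternatives *within* the
biological ranges the model is meant for; outside those ranges both aerobic
plateaus (thermal and anaerobic) break the exponential assumption, which is
why the data-filtering stage and the prediction guardrails exist.

The package ships two coefficient sets: `legacy_coefficients()`
$(61.6, -0.33, 1.03, 1.79)$, the long-serving industry-standard equation, and
`revised_coefficients()` $(79.7, -0.14, 1.04, 1.63)$, re-estimated from a
seven-study compilation of group swim-tunnel respirometry on a modern
domesticated strain.

## Data model and filters

One row of a `respirometry` dataset is a *replicate-aggregated entry*: the
mean MO~2~ of 2–6 replicate swim-tunnel trials at one unique
(study, treatment, body weight, temperature, relative speed) combination,
with the metadata needed by the filters. `aggregate_replicates()` performs
the collapse with unweighted means — group sizes vary for logistical, not
informational, reasons, so precision weighting would be spurious.

Two filter stages mirror how such a compilation is refined:

* `apply_inclusion_criteria()` keeps entries that are environmentally
  comparable: full-strength seawater, normoxia, at least three weeks of
  thermal acclimation (tunable via `min_acclimation_weeks`), healthy fish,
  and a fed state with only an overnight fast.
* `apply_model_assumption_filters()` removes observations where the
  exponential mean is known to fail: treatment groups at or above 23 °C
  (metabolic rate plateaus near the upper thermal tolerance) and speed steps
  at or above 100 % of the group's critical swimming speed (anaerobic
  recruitment plateaus MO~2~; the surviving maxima sit at 80–90 % of
  $U_\mathrm{crit}$). The 23 °C exclusion is generalised to a configurable
  `temp_cutoff` applied as $\ge$, which makes the rule reusable rather than a
  one-off row deletion. Entries with no recorded `pct_ucrit`
  (sustained-speed tests) are never removed by the speed rule: missing is
  not 100 %.

Each removed entry is attributed to the *first* rule it violates, and both
functions return a serialisable `filter_report`. On the emulated compiled
dataset the two stages take 96 raw entries to 76.

## Two-stage estimation

Estimation follows the two-stage tradition for multiplicative metabolic
models:

1. **Stage 1** (`fit_stage1_loglinear()`): the model is exactly linear on
   the log scale, $\log \mathrm{MO}_2 = \log a + b \log W + T \log c +
   U \log d$, so OLS gives closed-form, biologically interpretable starting
   values. Rank-deficient designs are refused with the collinear predictor
   named.
2. **Stage 2** (`fit_stage2_nlme()`): maximum likelihood on the *natural*
   scale with a per-study random intercept,
   $\mathrm{MO}_{2,ij} = (a + u_i) W^b c^T d^U + \varepsilon_{ij}$,
   $u_i \sim N(0, \sigma_s^2)$, $\varepsilon \sim N(0, \sigma^2)$.

The random effect is placed additively on the intercept. The source
tradition says only that study identity enters as a random effect; the
additive-intercept placement is the conventional reading, keeps the
conditional model linear in $u_i$, and makes the marginal covariance a
rank-one update — within study $i$, with $x_{ij} = W^b c^T d^U$,

$$y_i \sim N\!\big(a\,x_i,\; \sigma_s^2\,x_i x_i^\top + \sigma^2 I\big),$$

which `marginal_loglik()` evaluates exactly via the matrix determinant lemma
and the Sherman–Morrison identity (no factorisation, numerically stable for
any group size). Which parameter actually carried the random effect in the
original analysis is unknowable from the published description; only this
variant is implemented, and the synthetic generator draws from the same
variant, so estimator and generator are consistent by construction.

Maximum likelihood (not REML) is used deliberately: it matches the default
of the two-stage tradition and keeps the likelihood-ratio tests of the
interaction screen valid. With seven studies, ML variance components are
mildly shrunken; the Wald coverage checks in the test suite quantify the
practical effect (coverage ≈ 0.92–0.95 at the default study structure).

### Optimisation and numerical choices

* Parameters are optimised as $(a, b, \log c, \log d, \log\sigma_s,
  \log\sigma)$ — multipliers and variance components on the log scale for
  positivity; $b$ unconstrained.
* Quasi-Newton (L-BFGS-B, with parameter scaling) from the stage-1 start,
  $\sigma_{s,0} = 0.1\,a_0$ and $\sigma_0$ = stage-1 residual SD on the
  natural scale; then Newton polishing with Richardson-extrapolated
  gradients until the gradient infinity-norm over interior parameters drops
  below $10^{-6}$ (at most 500 quasi-Newton plus 50 polish iterations). A
  steepest-descent fallback handles indefinite-Hessian regions far from the
  optimum.
* $\sigma_s$ has an effective floor of $10^{-8} a_0$. A fitted $\sigma_s$
  below $10^{-3} a$ is statistically indistinguishable from zero yet leaves
  the likelihood almost flat in that direction (and the Hessian singular),
  so it is snapped to the floor and the remaining parameters re-polished;
  the induced likelihood change is below the convergence tolerance.
* Standard errors come from the inverse numerical Hessian (central
  differences, relative step $10^{-5}$) of the negative marginal
  log-likelihood over the interior parameters, delta-method-transformed to
  the natural $(a, b, c, d)$ scale. The Wald construction (rather than
  profile likelihood) is a choice; the source analysis does not state its
  interval method.
* With a single study $\sigma_s$ is unidentifiable and is fixed at zero with
  a warning. Non-convergence is reported in the `converged` flag, never as
  an exception. The optimiser is deterministic from its fixed start; an
  optional seeded multi-start (`multi_start = k`) jitters the start by 10 %.
* Entries are equally weighted regardless of group size or replicate count,
  matching the unweighted aggregation.

### Interaction screening

`screen_interactions()` adds one product term at a time inside the
exponential of the log-scale mean ($\log W \cdot T$, $\log W \cdot U$,
$T \cdot U$), refits, and compares by a 1-df likelihood-ratio test and AIC.
A candidate is supported when $p < \alpha$ *and* $\Delta\mathrm{AIC} < -2$;
when several are supported, one is retained only if it is a clear winner
(AIC at least 2 below the runner-up), otherwise none — without a clear
statistical winner there is no basis, and no biological rationale, for
preferring one product term over another. The published analysis states the
outcome (nothing retained) but no numeric criterion; this rule
operationalises it.

## Diagnostics and comparison

`model_diagnostics()` reports $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$,
adjusted $R^2$ with $p = 3$ predictors, $\mathrm{RMSE} =
\sqrt{\mathrm{SSE}/n}$, residuals, standardised residuals
(residual / $\hat\sigma$) and normal Q–Q pairs at plotting positions
$(i - 0.5)/n$. Fitted values use the fixed effects only by default
(`level = "population"`); `level = "conditional"` adds the empirical-Bayes
study deviations. How the published $R^2$/RMSE treat the random effect is
unstated, so both are implemented and the population version is the
default; RMSE uses $1/n$ (not $1/(n-p)$) normalisation, also configurable in
interpretation rather than silently divergent. `compare_models()` evaluates
the legacy equation *as published* against the same data — no refitting,
since the comparison of record is against the fixed legacy coefficients.

Derived quantities: `q10()` returns $c^{10}$, the multiplicative change per
10 °C; `coefficient_contrast()` reports the intercept rise in percent, the
absolute change in $b$, both Q10s, the relative change in per-10-°C
percentage sensitivity $100\,[(Q_{10}^{new}-1)-(Q_{10}^{old}-1)]/
(Q_{10}^{old}-1)$, and the percent change in $d$. Q10 overrides let the
contrast be computed at printed (rounded) Q10 values, which is how the
published 32 % sensitivity figure arises (from 1.34 and 1.45; recomputing
from the rounded $c$ values gives slightly different Q10s, e.g.
$1.04^{10} = 1.4802$).

`prediction_grid()` computes confidence bands by the delta method on
$\log \mathrm{MO}_2$ — gradient $(1/a, \log W, T, U)$ against the
optimisation-scale covariance — and exponentiates, keeping bands positive.
A parametric-bootstrap oracle in the test suite confirms the band widths to
well under 5 %.

## Extrapolation guardrails

`predict_guarded()` encodes where the exponential model can be trusted:

| axis | core (in_range) | extrapolated_ok | caution | refusal |
|------|----------------|-----------------|---------|---------|
| W (kg) | 0.205–3.38 | 0.1–6 | outside 0.1–6 | W ≤ 0 |
| T (°C) | 3–18 | 0–3 | 18–23 | T < 0 or T > 23 |
| U (BL/s) | 0.31–2.84 | 0–0.31 | > 2.84 | U < 0 |

Refusals are total: below 0 °C salmon cannot survive (plasma freezing), and
above ~23 °C the thermal plateau makes the exponential extrapolation
physiologically meaningless, so the tilde is resolved to an inclusive 23.0
cutoff. The upper speed band is a caution, not a refusal, because the
critical swimming speed is population-specific and unknown at prediction
time; callers get the 80–90 % $U_\mathrm{crit}$ ceiling message instead. An
oxygen saturation below 100 % appends a qualitative hypoxia caution — below
the limiting oxygen saturation the prediction is an overestimate — without
attempting any quantitative LOS arithmetic, which is out of scope.

## The synthetic-data generator

`default_synth_config()` encodes a seven-study layout whose coverage
(0.205–3.38 kg, 3–18 °C, 0.31–2.84 BL s^-1), per-study entry counts and raw
structure (96 entries, collapsing to 76 once the 23 °C group and the
100 %-$U_\mathrm{crit}$ steps are filtered) emulate the compiled dataset.
The generating truth defaults to the revised coefficient set with
$\sigma_s = 8$ (≈10 % of $a$) and $\sigma = 55$ mg O~2~ kg^-1^ h^-1^ —
tuning defaults chosen so a refit's residual scatter lands near the compiled
data's, not published values. Residual noise can instead scale with the
conditional mean (`cv_mode = "proportional"`) to mimic the mild
heteroscedasticity real respirometry shows at high fitted values. Negative
draws are redrawn rather than clipped — positivity without a point mass;
the bias is negligible at default noise levels since the smallest
conditional means sit near 120 while $\sigma = 55$. Plateau rows are
generated at $0.85\times$ the model extrapolation; the factor is arbitrary
but fixed and documented, since no plateau magnitude is published. Fork
lengths derive from weights at Fulton condition factor 1.2, typical of
farmed post-smolts.

What the generator does *not* emulate: real between-study differences in
design balance and measurement protocol, heteroscedasticity (in the default
constant mode), non-Gaussian residuals, within-group correlation beyond the
study intercept, and any genuine interaction structure. Passing the recovery
and screening tests therefore shows the estimator is correct *under its own
assumptions* — it does not certify the published coefficient values, which
can only be reproduced from the deposited compilation itself.

## What the tests establish

* Stage 1 recovers a noise-free truth to $10^{-10}$ relative error (the log
  model is exactly linear).
* The marginal likelihood matches a 2001-point quadrature oracle to
  $10^{-6}$ on a two-study toy, and matches `nlme`'s log-likelihood at
  `nlme`'s own optimum to $10^{-6}$.
* With $\sigma_s = 0$ the stage-2 estimates coincide with an independent
  Levenberg–Marquardt least-squares oracle to $10^{-4}$ relative.
* At the default seven-study structure over 200 seeds, the median estimate
  of each coefficient lands within 2 % ($a$, $c$, $d$) / 0.03 absolute ($b$)
  of the truth, and 95 % Wald intervals cover the truth with frequency
  0.92–0.95.
* The interaction screen holds its size under the interaction-free
  generator (200 seeds) and retains a planted $T \times U$ term of ≈10
  standard errors in at least 95 % of 100 seeds.

Simulation sizes (200 recovery seeds, 200 null-screen seeds, 100 power
seeds) were chosen to put Monte-Carlo error comfortably inside the asserted
tolerances while keeping the default test run to a few minutes on one core.

## Limitations

The model is a baseline for seawater post-smolts of one modern domesticated
strain: no feeding/digestion thermogenesis, photoperiod, handling stress,
parasite load, unsteady flow, or earlier life stages. Body weights between
roughly 1 and 3.3 kg are sparsely represented in the compilation the
generator emulates, so predictions there lean on the allometric form rather
than local data. Heteroscedasticity at high fitted values is acknowledged
but not modelled (no variance function), and sigmoidal plateau models for
$T$ and $U$ are deliberately out of scope — they would double the parameter
count and destroy the model's practical appeal.
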