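---
title: "Methods: multimodel screening of weevil-infestation predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodel screening of weevil-infestation predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the response variable

Andean potato weevils (*Premnotrypes* spp.) are flightless, tuber-boring
beetles; the damage a potato field suffers depends jointly on how the field
is managed (local features: insecticide timing, hilling, rotation, soil)
and on what surrounds it (landscape features: nearby potato storage units,
current-season and previous-season potato fields). `weevilrisk` screens
both feature classes jointly with an information-theoretic workflow over
ordinary least-squares models.

The response for a field is the proportion of infested tubers in its edge
and center strata, weight-averaged by the stratum areas, then square-root
transformed:

\[ y = \sqrt{\frac{p_e A_e + p_c A_c}{A_e + A_c}}. \]

The transform is applied *after* area-weighting; the reverse order differs
numerically and is not what `compute_response()` does. Proportions are
stored in [0, 1]; percentages are divided by 100 at ingest. Records with
missing values are rejected, not imputed.

## Model building and multimodel inference

All models are OLS fits scored by
\(\mathrm{AIC} = n \log(\mathrm{RSS}/n) + 2K\), with \(K\) the number of
regression coefficients (intercept included) plus one for the residual
variance. Additive constants of the Gaussian likelihood are omitted: only
differences between models fitted to the same response matter, and the
package's tests verify that differences agree with the full-likelihood
computation. Plain AIC is the default; the small-sample corrected version
(AICc) is available behind `corrected = TRUE` in every stage, because the
counting convention of the original software environment cannot be
recovered — the choice shifts all models of equal size equally and barely
moves the workflow's conclusions at \(n = 138\).

**Global model.** `build_global_model()` starts from the intercept-only
model and adds one variable at a time, always the candidate that lowers
AIC the most (ties break by pool order; candidates that would make the
design rank deficient are skipped with a warning). Additions continue past
the AIC minimum: a model is admitted as long as its AIC does not exceed
the running minimum by more than the tolerance (default 2.0, the
conventional radius of similar support). "Lowest AIC reached in previous
steps" is interpreted as the running minimum over the whole trajectory.
With tolerance 0 the procedure collapses to classical forward selection.
All candidates — including the observer-control indicators — compete on
equal terms, since in the source study the controls evidently entered the
global model through the same procedure.

**All-subsets enumeration.** `enumerate_and_fit()` fits every non-empty
subset of the selected variables (each with an intercept): \(2^p - 1\)
models, computed from cross-products with one small Cholesky solve per
subset in compiled code, deterministically. A guard rail refuses more than
20 variables unless overridden (hard cap 24). Subsets of a full-rank
design are full rank, so rank is checked once on the full design.

**Weights and averaging.** Within a model set,
\(w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)\). The confidence set
keeps models with \(\Delta \le 2.0\), boundary inclusive, and renormalizes.
A parameter's weight \(w_p\) is the summed weight of the models containing
it. The natural average is \(\sum_{i \ni p} w_i \hat\beta_i / w_p\); the
shrinkage average (used for prediction) is the natural average times
\(w_p\), exactly. The unconditional standard error is
\(\sqrt{\sum_{i \ni p} (w_i/w_p)\,[\widehat{var}(\hat\beta_i) +
(\hat\beta_i - \bar\beta)^2]}\) — the standard model-averaging variance
estimator, conditional on the models containing the parameter, with
a normal-approximation 95% interval (\(\pm 1.96\,\mathrm{SE}\)); the
source analysis reports symmetric intervals consistent with this but cites
no formula.

**Class comparison.** `compare_classes()` reruns the whole
stepwise-plus-enumeration procedure three times — local predictors only,
landscape predictors only, both — always with the observer controls in the
pool, and compares the three class-best models by AIC difference and
three-way Akaike weights.

## Derived outputs

**Standardized impacts** (`standardized_impacts()`): predictions use the
shrinkage coefficients at a baseline field with continuous variables at
their sample mean, ordinal/categorical variables at their sample mode
(ties to the lower level), and *all monthly insecticide counts at zero* —
the no-pesticide baseline deliberately overrides the mean rule for those
variables. Each variable is perturbed by +1 SD of its encoded column
(continuous/counts), +1 unit (ordinal/binary), or −1 unit for the number
of hillings, the only direction that keeps predictions within observed
bounds. Impacts are differences of squared sqrt-scale predictions
(percentage points), never a linear approximation; negative perturbed
sqrt-scale predictions are clamped at zero with a warning. Back-transform
is simple squaring; no retransformation bias correction is applied (the
source analysis gives no indication of one), which is flagged as a known
limitation.

**Insecticide efficacy** (`insecticide_model()`): one multiple regression
of the sqrt response on the December–March monthly treatment counts;
constant columns are dropped with a warning.

**Harvest adaptation** (`harvest_adaptation()`): a post-hoc simple
regression of harvest day on model-expected infestation, with
\(df = n - 2\) and a two-sided t-test. The pipeline feeds it
back-transformed (proportion-scale) predictions.

**Residual autocorrelation** (`correlogram()`): Moran's I
\(( n/S_0 ) \sum w_{ij} z_i z_j / \sum z_i^2\) per half-open 250 m distance
band \((d, d+250]\) up to 3 km (self-pairs excluded, planar Euclidean
distance, coordinates pre-projected in meters), with a permutation test:
residuals are permuted over locations (the same permutations across
bands), and the two-sided p-value is
\(\min(1,\; 2 \min(b_{lo}+1, b_{hi}+1)/(B+1))\) with the plus-one rule.
Sidedness is not specified by the source; two-sided is the conservative
default and makes the null p-values uniform, which the tests check. The
residuals tested default to the best (minimum-AIC) combined model;
averaged-model residuals are available via `residuals(fit, "averaged")`.

## The synthetic generator

The raw field records are not deposited, so the generator emulates the
printed study design and is itself first-class, tested code:

* **Design**: 138 fields, 4 observers assigned in near-equal blocks
  (35/35/34/34), one village-like coordinate cluster per observer
  (cluster SD 300 m, centers within ~2.1 km, supporting the 250 m/3 km
  correlogram design).
* **Covariates**: drawn independently per the registry. Continuous
  variables use left-truncated normals *moment-matched* so the sample mean
  and SD reproduce the survey table despite truncation; variables whose
  survey coefficient of variation exceeds what a left-truncated normal can
  reach (the two neighboring-potato percentages) use a moment-matched
  gamma instead. Monthly treatment and storage-unit counts are Poisson at
  the survey means (a Poisson is already nonnegative; no truncation point
  is printed). Binary and ordinal variables are sampled at the survey
  frequencies. The survey gives only marginal moments, so independence is
  the default — a known mismatch with real data, where e.g. elevation and
  landscape composition are correlated; soil fractions are drawn
  independently and need not sum to 100. A Gaussian-copula `correlation`
  hook on the continuous covariates lets users impose dependence without
  disturbing the margins (default identity). Passing tests therefore show
  the *procedure* behaves correctly under the stated marginal structure,
  not that it is robust to real-world covariate correlation.
* **Response**: \(y = \beta_0 + \sum \beta_j x_j + \text{observer offset}
  + \varepsilon\) on the sqrt scale, squared into a field proportion
  (clamped to [0, 1]). True effects are the published weight-averaged
  estimates; unsupported variables have effect zero; observer offsets are
  (0, −0.043, −0.070, 0), matching the two reported observer effects with
  two reference-level observers. The published intercept (1.774) is
  conditional on the real data's covariate configuration and does not
  reproduce the observed mean infestation under the registry's marginal
  means — the default intercept is instead derived so the expected
  sqrt-scale response equals \(\sqrt{0.183}\) (the reported 18.3% mean).
* **Strata**: the field proportion splits into edge and center strata with
  the reported 25.1/18.3 and 16.1/18.3 ratios, renormalized to preserve
  the area-weighted mean; total areas follow the reported 424.6 ± 282.4
  m² (truncated at 30 m²), and the edge share uses the square-ring
  approximation \(3r - 2.25 r^2\) of the field's perimeter-to-area ratio.
* **Noise calibration**: the residual SD is the one free parameter. The
  package default (`default_truth()`) was produced by `calibrate_sigma()`
  — bisection on \(\sigma\) until the *median best-model R²* (the
  minimum-AIC model from the all-subsets enumeration of the stepwise
  selection) over 20 simulated datasets falls inside the reported
  40.2–46.4% band, at n = 138 with seed 20090501. It is frozen as a
  constant so that every downstream test and script sees the same
  conditions.

## Numerical choices and degenerate inputs

* Ties in forward selection break by pool order; bimodal ordinal baselines
  take the lower level; the confidence-set boundary is inclusive
  (\(\Delta \le 2\)).
* A saturated fit (RSS = 0) has no finite criterion: `aic()` raises a
  degenerate-fit error and `fit_ols()` records `NA`.
* Zero-variance inputs raise classed errors (`moran_i` on constant
  vectors, `harvest_adaptation` on constant expectations,
  `calibrate_sigma` with no signal, where explained variance is invariant
  to \(\sigma\) and the band is reported as unreachable).
* Enumeration problem sizes: the package's own test and acceptance runs
  use 20 replicates of the full pipeline and 200 replicates of a
  ten-variable averaging design — sizes chosen to pin the stochastic
  checks' Monte-Carlo error well below their tolerances while keeping a
  full suite run in minutes on a laptop.

## Known limitations

* Independence of covariates in the generator (see above); a correlation
  hook would require information the survey does not print.
* No interaction terms, by design of the source analysis.
* No GLS/mixed models, no branch-and-bound subset search (exhaustive
  enumeration is the method under test), no variogram fitting or
  spatially adjusted regression.
* The generator emits field-level proportions directly; it does not
  simulate tuber-level sampling of the 40 plants per field.
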