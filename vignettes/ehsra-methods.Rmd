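---
title: "EHSRA: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EHSRA: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehsra)
```

# The model

Occupational heat strain is treated as a single latent variable measured by
six observed indicators — dry, natural wet-bulb and globe temperatures
(°C), air velocity (m/s), total metabolism (W) and clothing insulation
(clo) — with one structural path from the latent factor to tympanic
temperature (°C), the gold-standard proxy for core temperature:

$$x_i = \lambda_i \eta + \delta_i, \qquad y = \gamma \eta + \varepsilon,
\qquad \mathrm{Var}(\eta) = 1 .$$

The standardized loading $\lambda_i$ is each variable's *direct effect* on
heat strain; its *indirect effect* on tympanic temperature is
$\lambda_i\gamma$, an algebraic identity of the single-path topology. The
calibrated structural coefficient is $\gamma = 0.801$, and the six indirect
effects (0.752, 0.686, 0.774, 0.244, 0.491, 0.387) are the weights of the
index:

$$\mathrm{EHSRA} = 10 \sum_{i=1}^{6} c_i \,
\frac{x_i - \min_i}{\mathrm{range}_i},$$

with the air-velocity term entering negatively when dry temperature is
below skin temperature (35 °C): moving air then cools rather than heats.
Scores fall into four risk bands whose boundaries (12.02, 15.88, 17.56)
were chosen as the ROC points nearest the ideal (sensitivity 1,
specificity 1) corner when dichotomizing tympanic temperature at 37.5,
38.0 and 38.5 °C.

## Estimation

`fit_path_model()` minimizes the Wishart maximum-likelihood discrepancy

$$F(\theta) = \log|\Sigma(\theta)| + \mathrm{tr}\,(S\,\Sigma(\theta)^{-1})
- \log|S| - p$$

by BFGS with an analytic gradient ($dF = \mathrm{tr}[(\Sigma^{-1} -
\Sigma^{-1}S\Sigma^{-1})\,d\Sigma]$). Error variances are log-parameterized,
which keeps $\Sigma(\theta)$ positive definite along the search path for
the default topology. $\chi^2 = (n-1)F(\hat\theta)$, and the fit indices
use their standard definitions (GFI, AGFI, NFI, CFI, IFI, RMSEA, normed
$\chi^2$) with the independence model
($\chi^2_0 = -(n-1)\log|R|$, $df_0 = p(p-1)/2$) as baseline.

Numerical choices:

* **Identification.** Latent variance fixed at 1 with all six loadings
  free. Six standardized loadings plus a structural coefficient are
  reported, which rules out marker-variable scaling.
* **Start values.** Deterministic: $\lambda_i^{(0)} = 0.7\,s_i$,
  $\psi_i^{(0)} = s_i^2/2$; no random restarts. Convergence requires a
  gradient norm $\le 10^{-8}$ (relaxed to $10^{-4}$ when the line search
  terminates cleanly first) within 500 iterations; failure is flagged on
  the returned object, never silent.
* **Factor sign.** The factor's sign is unidentified; the fitted solution
  is reflected to a majority-positive loading pattern.
* **Heywood cases.** Standardized loadings outside $[-1, 1]$ are reported
  with a warning, not truncated.
* **Topology.** The published normed $\chi^2$ (1.364 with $p = 0.234$)
  implies $df = 5$, i.e. several indicator error covariances beyond the
  14-parameter simple model; their exact placement is not recoverable from
  the text. The default model is therefore the *simple* one-factor model
  ($df = 14$), and `path_model_spec(error_cov = ...)` accepts an explicit
  list for users who wish to explore richer topologies. The published fit
  indices are consequently **not** reproduction targets; the fit-index code
  is instead verified against closed forms (e.g. RMSEA at $\chi^2 = 6.82$,
  $df = 5$, $n = 201$ is $\sqrt{1.82/1000} = 0.0427$).

A second, deliberately independent fitting route (the same discrepancy
re-derived with `determinant()`/`solve()` and optimized by `nlminb` from
perturbed starts) serves as the test oracle; no general-purpose SEM package
is used anywhere.

## ROC calibration

`roc_curve()` uses candidate thresholds at midpoints between consecutive
distinct scores plus $\pm\infty$ sentinels, predicting positive when
score $\ge$ threshold. AUC is the Mann–Whitney pair statistic (ties count
½), which equals the trapezoidal area under this curve; its 95% interval
uses the Hanley–McNeil normal approximation, consistent with the symmetric
intervals the calibration study reports. `optimal_cutpoint()` minimizes
$\sqrt{(1-\mathrm{sens})^2 + (1-\mathrm{spec})^2}$, breaking ties toward
higher sensitivity and then the lower threshold. Tympanic dichotomization
is strict (`> boundary`): the boundary itself is not "exceeding".
`derive_risk_bands()` refuses to reorder crossed cut-points — a
non-monotone calibration is an error, not something to patch silently —
and rounds reported cut-offs to 2 decimals, the printed precision.

## Validation

`validate_regression()` is ordinary least squares of tympanic temperature
on the score. `closed_form_r2()` is an analytic oracle needing only
printed summary tables: with weights $w_i = c_i\,s_i/\mathrm{range}_i$,
predictor correlation block $R$ and outcome correlation column $r$,

$$R^2 = \frac{(w^\top r)^2}{w^\top R w},$$

invariant to the overall ×10 scale and to any common rescaling of the
weights. The closed form describes the *linear* combination (positive
air-velocity sign). The deployed score is piecewise linear because of the
per-sample sign rule; with the calibration-study moments (pooled dry
temperature well below 35 °C) the two differ only slightly — Monte-Carlo
regression of the piecewise score on a 10⁵-record synthetic cohort gives
R² ≈ 0.747 against the closed form's 0.752, both 0.75 at the printed
precision. The package scores with the per-sample rule and validates with
the linear oracle, and the test suite ties the two together.

# The synthetic cohort

No raw data accompany the calibration study, so `default_cohort_model()`
bakes in its printed second-moment structure: per-variable means and SDs,
the 7×7 Pearson correlation matrix (globe–tympanic 0.766, dry–tympanic
0.751, wet–tympanic 0.685, …), the observed hard ranges, and the two-site
climatic overrides (hot-dry steel vs hot-humid petrochemical, mixed
111 : 90). `sample_cohort()` draws multivariate-normal records via a
Cholesky transform — the study itself reports normally distributed
variables — with options the defaults deliberately leave off:

* **Truncation** to the observed ranges is off because rejection sampling
  distorts the calibrated moments; the working tympanic range
  (36.7–39.1 °C) is respected approximately, not enforced.
* **Demographics** (age, heart rate; used only by the screening rules
  `hrmax()` and `apply_screening()`) are drawn independently of the
  thermal block: the published tables give no cross-correlations.
* The printed pooled dry-temperature mean (24.78 °C) is inconsistent with
  the per-site means (33.58 / 36.26 °C) — likely a misprint. The pooled
  table is used verbatim; every correlation-based target is unaffected by
  means, which is also why the t8 acceptance target is a correlation.

What a green test does and does not establish: the generator matches the
study's first and second moments, so moment-determined quantities
(correlations, the closed-form R², SEM inputs) are faithfully emulated.
It does **not** reproduce the raw joint distribution, so the published ROC
cut-offs (12.02/15.88/17.56), their sensitivity/specificity pairs and AUCs
are *not* recoverable from synthetic data — the acceptance suite
substitutes exhaustive brute-force equivalence checks for the ROC
machinery instead (every distinguishable labelled dataset of size ≤ 12
over a 4-letter score alphabet, enumerated as count vectors over the eight
(score, label) symbols).

# Index conventions and edge cases

* **Band edges.** The printed band table ("12.02 to 15.87", "15.88 to
  17.56") leaves continuous scores in (15.87, 15.88) unassigned. Bands are
  closed at their lower bounds, with the top band strictly open
  (`> 17.56`), so High is effectively [15.88, 17.56]; rounding scores to
  2 dp reproduces the printed table exactly.
* **Sign rule at exactly 35 °C.** The rule is stated as "lower than" skin
  temperature, so equality keeps the positive sign.
* **Out-of-calibration input** is never clipped: normalized values may
  leave [0, 1], with a warning, because silent clipping would hide
  extrapolation beyond the ranges the weights were calibrated on.
  `check = FALSE` additionally waives the physical bounds
  (`v_air ≥ 0`, etc.) for raw synthetic draws.
* **Globe denominator.** The published formula's globe range (39.30)
  differs from the summary table's 62.43 − 23.40 = 39.03; the formula
  constants are canonical, the discrepancy is documented.
* **Dry above globe** temperature is physically unusual but accepted with
  a warning; repeated measurements aggregate as mean (thermal) and
  maximum (physiological), per the study protocol.

# Known limitations

* Only this model family: one latent factor, one outcome, optional
  indicator error covariances — no multiple latents, mean structures,
  categorical indicators or missing-data ML.
* Cut-point criteria other than nearest-to-ideal (Youden, cost-weighted)
  and bootstrap AUC intervals are out of scope.
* Metabolism and clothing insulation must be supplied as numbers;
  estimating them from task or garment descriptions is not attempted.
* The synthetic two-site mode overrides only the climatic variables the
  site tables publish (dry/wet/globe); the remaining variables keep pooled
  moments and the pooled correlation structure.
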