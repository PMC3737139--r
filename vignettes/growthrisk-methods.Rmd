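---
title: "Methods and design notes for growthrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for growthrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthrisk)
```

## The problem and the model

Accelerated weight gain in infancy, together with higher birth weight, is a
robust early predictor of childhood obesity. `growthrisk` packages a
screening approach built on that evidence: an infant seen once between 4.5
and 13.5 months of age is scored with a logistic equation whose inputs are
sex, the birthweight z-score, and the conditional weight z-score gain from
birth to the assessment, optionally augmented with maternal BMI. The score
is the predicted probability of a composite outcome at age 2 years — BMI
above the 91st centile *and* conditional weight gain from birth to 2 years
above one centile band — and is reported as a low/medium/high band.

Three equations cover the assessment span, one per window (6, 9 and 12
months, each ± 1.5 months, mapped half-open in months with 1 month defined
as 30.4375 days). Each window has a base variant and a maternal-BMI
variant; the variant is chosen by whether both maternal height and weight
are available, because in practice maternal anthropometry is often
unavailable or withheld. The six coefficient vectors and their banding
thresholds are embedded constants (`published_equations()`); the
development pipeline in this package can re-derive equations of the same
form from any cohort table.

## Z-scores and the LMS reference

All anthropometry is z-scored by the LMS method. For reference curves
$L(t)$, $M(t)$, $S(t)$,

$$z = \frac{(x/M)^{L} - 1}{L\,S}, \qquad z \xrightarrow{L \to 0} \frac{\log(x/M)}{S},$$

with the logarithmic limit taken whenever $|L| < 10^{-7}$ (the two forms
agree to well below measurement precision there, so the switch is
continuous in practice). $L$, $M$ and $S$ are interpolated **linearly in
age (days)** between tabulated knots — the reference tables themselves do
not state an interpolation rule for untabulated ages, so linearity is this
package's choice: it is standard LMS practice, cheap, and preserves
monotonicity of $z$ in $x$ at every age.

National reference tables (such as the UK90 tables the scoring approach is
defined against) are licensed and are not redistributed here. The package
instead ships `synthetic_lms_reference()`: smooth closed-form L/M/S curves
over 0–30 months with the qualitative shape of UK infant references
(decelerating weight growth from ~3.4 kg, BMI peaking near 8 months, boys
a few percent heavier). It is deterministic, clearly labelled synthetic,
and exists so that every example and test runs without a download; it must
not be used for clinical interpretation. Users with access to a real
reference supply it as a CSV (`measurement,sex,age_days,L,M,S`) through
`read_lms_reference()`.

## Conditional weight gain

Raw z-score change $z_t - z_0$ is negatively correlated with starting size
(regression to the mean). The conditional gain used throughout is the
standardized residual of the follow-up z on the baseline z:

$$g = \frac{z_t - (a + b\,z_0)}{s},$$

where $a, b$ come from OLS and $s$ is the root mean square residual with an
$n-2$ denominator. By construction $g$ has mean 0, SD 1 and zero
correlation with $z_0$ in the fitting sample — asserted on every fitted
model in the test suite. Two open choices had to be made:

* **Where the conditioning constants come from.** The constants are
  estimated within the analysis cohort when developing equations (per
  equation sample); for scoring a new infant an externally supplied
  `conditional_model()` is accepted, and `default_conditional_model()`
  carries $r = 0.5$ (`a = 0`, `b = 0.5`, `s = \sqrt{0.75}`), a typical
  birth-to-infancy weight-tracking correlation. The source analysis does
  not state which convention its app used, so the constants are explicit
  and configurable rather than hidden.
* **"One centile band".** UK growth charts draw their major centile lines
  2/3 of an SD apart, so the outcome's gain condition defaults to 0.67 SD.
  The comparator is strict (`>`) by default because the outcome definition
  reads "greater than one centile band", but a footnote-style `>=` variant
  is available in `outcome_rule()` since both readings appear in
  descriptions of the outcome.

When the 2-year measurement window (±2 months) contains more than one
measurement, the nearest in time would be selected; the package's own
generator emits exactly one measurement per window, and multi-visit
selection is otherwise left to the user's data preparation.

## The scoring equations and banding

The published footnote form of the risk score omits the covariate products;
it is implemented as the standard linear predictor
$\alpha + \beta_1 \mathbf{1}[\text{female}] + \beta_2 z_{bw} + \beta_3 g
(+ \beta_4 \text{mBMI})$, which is confirmed by the development odds-ratio
table equalling $e^{\beta}$ of the embedded coefficients (e.g.
$e^{0.824} = 2.28$ for the 12-month birthweight coefficient).

Banding uses the development-sample score-distribution thresholds printed
with the equations: `high` for scores in the top decile ($p \ge t_{10}$),
`medium` between the decile and quintile thresholds, `low` below. The
prose description of the band boundaries in the source is internally
inconsistent (it reads as "above 20% low"); the implemented reading —
top decile high, decile-to-quintile medium, rest low — is the only one
consistent with choosing the 10% cut-off *as* the high-risk threshold and
with the threshold ordering $t_{10} > t_{20} > t_{30}$. This is a
documented interpretation, not a claim about the original authors' intent.

## Model development

`fit_logistic()` is a Newton/IRLS maximizer written for this package so
that its failure modes are explicit: it stops when the score norm falls
below $10^{-8}$, errors after 100 iterations, errors on rank-deficient
designs, and detects complete separation (diverging coefficients whose
direction perfectly splits the classes) instead of returning a silently
divergent fit. Tests cross-check it against `stats::glm` and against
brute-force grid maximization of the log-likelihood.

`backward_stepwise()` removes the least significant term (Wald test;
$\chi^2_k$ for $k$-column terms) at or above $\alpha = 0.05$ per pass.
Design choices, each made where the described procedure was silent:

* **Wald p-values**, matching common stepwise output; likelihood-ratio
  tests would change little at these sample sizes.
* **Ties** are broken by removing the later term in declared candidate
  order, making the procedure deterministic.
* **Interaction hierarchy**: only the four screened interactions (sex or
  ethnicity × birthweight z or gain z) are allowed; an interaction is
  removable before its main effects, and a main effect is locked while a
  retained interaction contains it.
* **Education enters as a block** of four dummies, removed or retained
  jointly — partial categories of an ordinal-ish factor are not
  interpretable.
* **Sex can be forced** (`forced = "sex"`) when developing scoring
  equations, mirroring final equations that keep sex regardless of its
  p-value while the development table omits it.
* **Rank deficiency** (e.g. duplicated covariates) is repaired before
  fitting by dropping the later-declared offending term, recorded in the
  result.

## Validation

* **AUC** is the Mann–Whitney estimator via mid-ranks (exactly equal to
  exhaustive pair counting, ties ½), with DeLong placement-value variance
  for the CI — cross-checked against `pROC` in the tests.
* **Threshold diagnostics** place the cut-off at the empirical order
  statistic at $\lceil (1-q)n \rceil$ with ties admitted above
  (test-positive means score ≥ threshold), for $q$ = 30/20/10%. This rule
  reproduces published-style tables under integer back-solving (e.g. a
  731-subject table with 61 cases at the 10% cut-off implies 74
  test-positives). Rate CIs are exact Clopper–Pearson.
* **Bootstrap internal validation** resamples at the original $n$, re-runs
  the full selection on each resample, and summarizes terms by a 95%
  percentile rule (a term enters the final bootstrap model if its
  percentile interval — with 0 contributed by reps that dropped it —
  excludes 0; a ≥ 50% retention-frequency rule is available). The final
  bootstrap model is refitted on the original sample and its AUC reported
  there. Both summary rules are labelled interpretations: the source
  describes the outcome of its bootstrap ("retained the same variables")
  but not the mechanism. Resamples that fail (separation) are skipped and
  counted.
* **External validation** applies frozen coefficients to a new cohort and
  reports the AUC — no refitting.

## Synthetic cohorts

`simulate_model_mode()` draws covariates independently — sex, birthweight z
(default mean −0.56, SD 1.2), conditional gain z (mean 0, SD 1), maternal
BMI (25.9, SD 5.6, truncated to 13–60 kg/m² by rejection), ethnicity,
education, smoking, gestational diabetes, preterm — and draws the outcome
from the configured equation's logistic model. Independence of gain from
birthweight z is justified because the conditional gain is by construction
the standardized residual on birthweight z; the joint distribution of the
remaining covariates in real cohorts is not reported, so independence is
assumed and flagged as a limitation. Prevalence is emergent (≈ 6–9% under
the default presets), never forced, so that parameter-recovery tests are
not circular.

`simulate_growth_mode()` instead draws a latent correlated weight-z process
(birth/assessment/2 years; defaults $r$ = 0.5/0.45/0.75, BMI z correlated
0.8 with 2-year weight z), inverts it through the LMS reference to raw
weights (the 2-year length is set so weight and length reproduce the
latent BMI z), and computes outcomes with the composite rule. This
exercises the full raw-measurement path: z-scoring the emitted
measurements recovers the latent z to 10⁻⁶.

`bib_preset()` carries the per-window development-sample moments;
`external_preset()` the leaner, almost entirely White external-sample
profile (maternal BMI 23.4, SD 4.0; birthweight z ≈ −0.06, SD 1.04).

**What passing tests show — and don't.** The generators emulate first and
second moments and the logistic data-generating process. Real cohort
covariates are only approximately Gaussian, are mutually correlated, and
contain measurement error and missingness the generators omit. Agreement
of simulated AUCs and sensitivities with published values (within their
confidence intervals) therefore demonstrates internal consistency of the
implemented equations with their reported discrimination, not a
reproduction of the original cohort analyses.

## Numerical choices and problem sizes

* Ages are whole days internally; months are days/30.4375 everywhere.
* $|L| < 10^{-7}$ switches the LMS transform to its log-limit form.
* IRLS: score tolerance $10^{-8}$, 100-iteration cap, Newton steps damped
  to a max-norm of 20 far from the optimum.
* Unit conversions are exact constants: 1 lb = 0.45359237 kg,
  1 in = 2.54 cm.
* OR intervals use $z_{0.975} = 1.959964$.
* Test and acceptance problem sizes were chosen as the smallest that make
  Monte-Carlo error comfortably smaller than the assertion bands:
  parameter recovery at $n = 10^5$, discrimination and threshold
  diagnostics at $n = 2\times10^5$, bootstrap at $B = 200$ on $n = 2000$,
  null-retention rate over 120–200 replicates.

## Known limitations

* The embedded equations were developed in one UK region with a
  White-British/South-Asian cohort; generalization elsewhere is untested
  here, as is any use outside 4.5–13.5 months of age.
* The shipped reference is synthetic; all clinically meaningful use
  requires a real LMS reference table.
* The outcome is risk at age 2, not confirmed obesity in later childhood.
* Exact published score thresholds and external-sample AUCs depend on the
  original cohort data, which are not public; this package checks the
  consistency relations that are reproducible at the desk (coefficient/OR
  identities, 2×2 back-solving, simulation-based discrimination) and
  treats the rest qualitatively through the presets.
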