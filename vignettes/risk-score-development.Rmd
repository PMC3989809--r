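---
title: "Developing and validating an integer risk score for renal artery stenosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and validating an integer risk score for renal artery stenosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(rascore)
```

## The problem

Significant renal artery stenosis (RAS, a lumen narrowing of at least
50% on renal angiography) is found in roughly one patient in ten
undergoing elective coronary angiography, and it is an independent
marker of cardiovascular risk. Routine "drive-by" renal angiography in
every patient is hard to justify, so clinicians want a bedside rule
that flags the patients worth imaging. `rascore` implements the full
statistical workflow by which such integer point scores are built from
a development cohort and validated internally:

1. dichotomize each continuous predictor at its Youden-optimal ROC
   cut-point;
2. fit a multivariable logistic model and reduce it by backward
   elimination on Wald statistics;
3. estimate the optimism of the model's discrimination by re-running
   the *entire* pipeline on bootstrap resamples;
4. convert the retained coefficients into integer points and calibrate
   the score-to-probability mapping;
5. evaluate the score (discrimination, classification metrics,
   goodness of fit) on patient-level or grouped data.

The package ships the published reference artefacts of one such score
(its eight model coefficients and its grouped development table) so the
score machinery can be exercised on real printed numbers, and a
synthetic-cohort generator so the stochastic stages can be tested end
to end without patient data.

## The model

For patient $i$ with indicator covariates $x_{i1},\dots,x_{ik}$ the
outcome model is ordinary logistic regression,

$$\log \frac{P(Y_i = 1)}{1 - P(Y_i = 1)} = \alpha + \sum_k \beta_k x_{ik},$$

fitted by maximum likelihood. All predictors enter as 0/1 indicators;
carotid-plaque extent is a three-level categorical (none / unilateral /
bilateral) entering as two dummies against "none" and treated as a
single block.

The indicators come from fixed clinical conventions plus data-driven
cut-points:

* age, carotid intima-media thickness (CIMT), total cholesterol, HDL
  cholesterol and triglyceride are "at risk" **at or above** their
  cut-off;
* body-mass index is "at risk" **strictly below** its cut-off (low BMI
  marks poor general condition in this population);
* four or more anti-hypertensive medications is a fixed clinical
  category, not a derived cut-point;
* chronic kidney disease stage $\geq 3$ is eGFR $< 60$
  ml/min/1.73 m^2 (strict), with eGFR from the 4-variable
  IDMS-traceable MDRD equation
  $175 \cdot \mathrm{Scr}^{-1.154} \cdot \mathrm{age}^{-0.203} \cdot
  0.742^{[\mathrm{female}]}$. The race factor is omitted because the
  intended cohorts do not collect it; the constant is overridable in
  `compute_egfr()`.
* proteinuria is a urine protein/creatinine ratio strictly above
  300 mg/g; records with a missing ratio are treated as non-proteinuric
  and counted in a completeness attribute rather than dropped, since
  the variable rarely survives elimination.

### Cut-point selection

`youden_cutpoint()` maximizes $J = \text{sensitivity} +
\text{specificity} - 1$ over the *observed* values of the predictor.
Observed-value thresholds (rather than midpoints) make a reported
cut-off an attainable data value, so the rule "CIMT $\geq$ 1.0 mm" can
be read straight off the result. Two numerical choices matter and are
deliberate:

* $J$ is compared on the exact integer scale $J \cdot n_1 n_0$, so
  ties are real ties and are broken towards the smaller cut-off — the
  selection is fully deterministic and invariant to row order;
* when no direction is supplied, the direction whose AUC is at least
  0.5 is used; in the model-development pipeline the directions are
  fixed by the conventions above instead, so a resample cannot flip a
  variable's clinical meaning.

### Backward elimination

`backward_select()` refits after removing the term with the largest
Wald p-value among those with $p \geq 0.10$; the relatively permissive
exit threshold retains modestly significant predictors. The categorical
plaque block is tested with a 2-df Wald statistic and removed (or kept)
as a whole: level-wise removal would leave an uninterpretable dummy
and, in the reference model, the unilateral level alone would sit just
above a 0.05 line while the block is clearly significant.

Two degeneracies arise routinely inside bootstrap resamples and are
handled rather than fatal: a term that is constant in the resample is
dropped up front with a log entry, and a term that produces complete or
quasi-complete separation (coefficient diverging past 15 on the
log-odds scale with a non-vanishing score component) is removed with a
logged warning. Penalized (Firth-style) fitting was deliberately not
made the default because it changes the estimator away from plain
maximum likelihood; dropping the offending term keeps the estimator
identical to the reference procedure on the vast majority of resamples.

### Fitting details

`fit_logistic()` is iteratively reweighted least squares with
convergence declared when the largest score component falls below
1e-8 or the relative log-likelihood change falls below 1e-10, capped at
50 iterations. At convergence the score identity
$X^\top(y - \hat p) = 0$ holds, which the tests verify directly; it
implies fitted probabilities sum to the event count. Wald intervals are
reported at both 90% and 95% because score development traditionally
inspects both when a predictor hovers near the exit threshold.

## Internal validation

`bootstrap_validate()` draws resamples of size $n$ with replacement
and re-runs the *whole* pipeline on each — new Youden cut-points, new
dichotomization, new backward elimination — because the cut-points and
the selection path are part of the modelling procedure, and validating
only the final refit would understate optimism. For resample $b$ the
model's AUC on its own resample ($C^{boot}_b$) and on the original data
($C^{orig}_b$) give

$$\hat O = \frac{1}{M}\sum_b \left(C^{boot}_b - C^{orig}_b\right),
\qquad \text{AUC}_{corrected} = \text{AUC}_{apparent} - \hat O.$$

This is the standard optimism-corrected bootstrap; the subtraction is
oriented so that the corrected AUC is the apparent AUC minus a
non-negative-in-expectation optimism. (Some published descriptions
print the difference in the opposite order while reporting arithmetic
consistent with this orientation; the arithmetic wins.) The procedure
is often loosely called a "0.632 bootstrap" in the clinical literature;
the genuine Efron 0.632 estimator
$0.632 \cdot \overline{C^{oob}} + 0.368 \cdot \text{AUC}_{apparent}$
is computed alongside from the out-of-bag subjects and reported as
`auc_632` for comparison, but the optimism-corrected value is the
headline number. Resamples on which the pipeline fails are skipped and
counted; more than 20% failures flags the report.

Calibration is summarised by locally weighted scatterplot smoothing of
the observed outcome on the predicted probability (tricube-weighted
local linear regression, span 0.75 by default, no robustness
iterations since the response is binary). The mean and 0.9-quantile of
the absolute difference between the smoothed observed probability and
the prediction summarise miscalibration on the probability scale.

## The integer score

With retained coefficients $\beta_{(1)} \leq \dots \leq \beta_{(k)}$,
each predictor receives the integer nearest to
$\beta_{(j)} / \beta_{(1)}$ — the weakest predictor anchors the scale
at 1 point. Exact halves round away from zero; no published ratio
lands on a half, so this convention is inert on the reference values
but makes the rule total. The maximum total counts mutually exclusive
plaque levels only once (at the larger value). For the published model
this yields points of 2 (significant coronary disease, bilateral
plaque, kidney disease stage $\geq 3$, four or more medications) and 1
(unilateral plaque, CIMT, age, low BMI), with totals spanning 0–11:

```{r}
sys <- derive_scores(reference_coefficients())
sys
```

`calibrate_score()` then fits $\text{logit}(p) = a + b \cdot
\text{score}$ by maximum likelihood (grouped tables are expanded to
subjects; the weighted fit is identical), giving the predicted event
frequency $n_s \cdot p(s)$ at each score:

```{r}
cal <- calibrate_score(reference_score_table(), sys)
cal$predicted
```

### Evaluation on grouped data

Published development tables arrive as (score, n, events) rows, so the
evaluation statistics are computed directly on grouped counts:

* `grouped_auc()` is the tie-corrected Mann–Whitney statistic
  $(\text{wins} + \tfrac12\,\text{ties}) / (n_1 n_0)$, identical (to
  1e-12, and verified against a pairwise enumeration oracle) to the
  trapezoidal area on the expanded subjects. The confidence interval
  uses the DeLong placement-value variance on the logit scale so it
  respects [0, 1]; a published interval computed by another variance
  recipe may differ slightly in width.
* `classification_metrics()` reports sensitivity and specificity at
  "score $\geq$ cut-off", and predictive values both raw (from the
  table's own counts) and prevalence-adjusted by Bayes' formulas. Both
  are reported deliberately: at the development prevalence they agree
  to rounding, but readers quoting one or the other can check either.
  (On the reference table the raw negative predictive value is 97.9%
  while 97.7% circulates in print; neither the raw nor the
  prevalence-adjusted computation yields 97.7%, so both defensible
  values are exposed and no agreement is forced.)
* `hosmer_lemeshow()` groups by the observed score values — the table
  *is* the grouping — with $df = \text{groups} - 2$ by default for the
  two calibration parameters. The df convention is exposed because
  software differs; on the reference table the p-value is insensitive
  to the choice at any conventional level.
* `fit_goodness_r2()` is the ordinary least-squares $R^2$ of observed
  on predicted per-score event frequencies. The nonlinear-regression
  flavour of this statistic that sometimes appears in print is not
  reproduced: with a fitted two-parameter logistic already in hand, OLS
  on the predicted frequencies is the transparent choice, and the
  printed values are treated as lower-bound checks only.
* `delong_compare()` implements the paired DeLong test via placement
  values; it is exactly rank-invariant, so comparing a score with any
  monotone transform of itself gives a difference of zero.

## The synthetic cohort generator

`generate_cohort()` emulates the development setting: 641 patients,
9.4% outcome prevalence, covariate marginals matched to the published
baseline table (truncated normals for age, BMI and total cholesterol;
log-normals matched to the printed medians/IQRs or mean/SD for HDL,
triglyceride, creatinine, urine protein/creatinine ratio and CIMT;
binary prevalences of 0.61 hypertension, 0.278 diabetes, 0.27 smoking,
0.26 coronary disease, 0.49 male; plaque extent multinomial
(0.58, 0.21, 0.21) — the published overall plaque prevalence pins down
only the 42% total, so the unilateral/bilateral split is an even,
configurable choice). Medication counts are Poisson(1.6), matching the
printed mean; the implied rate of "four or more" is then about 8%,
which is consistent with that category's strong observed effect.

The outcome is drawn from the indicator-based logistic model with the
published coefficients — the final model is indicator-based, so
generating from indicators makes the generator's truth exactly
recoverable by the fitting machinery. The intercept is solved by
monotone bisection (`solve_intercept()`) so the marginal event
probability hits the target prevalence to within 5e-4 over a 200,000
draw Monte-Carlo sample.

Covariates are independent by default: the published variance-inflation
factors average 1.19 with a maximum below 1.4, i.e. near-orthogonality,
and independence is the simplest structure consistent with that. A
Gaussian-copula correlation matrix can be supplied for collinearity
stress tests.

What the generator does **not** emulate: the joint dependence of real
risk factors (age–kidney-function, plaque–CIMT correlations), any
continuous-scale effect of the dichotomized variables on the outcome,
measurement error in ultrasound readings, and site-specific selection
into angiography. Passing tests on synthetic cohorts therefore
demonstrate that the *procedures* are correct and stable under the
stated sampling model — not that the published score generalises to new
patients.

## Problem sizes used by the test suite

The suite exercises the pipeline at the development size (n = 641) for
bootstrap validation (200 resamples per seed across 20 seeds), at
n = 50,000 for coefficient recovery, and at 100,000 draws for
prevalence control; oracle comparisons (pairwise AUC, exhaustive Youden
search, numeric likelihood maximization) run on 200 randomized small
instances each. These sizes give Monte-Carlo error comfortably inside
the asserted envelopes while keeping a full run in the minutes range.
One deliberate caveat: requiring every one of 8 coefficients within
±0.1 of truth in every replicate is a demand of about 2–4 standard
errors simultaneously on 160 estimates, so isolated excursions just
past 0.1 are expected statistically; the per-replicate proportion
within tolerance is the stable quantity.

## Known limitations

* The pipeline assumes complete rows for the modelling variables;
  beyond the urine-ratio rule above there is no imputation. Cohorts
  with missing laboratory data should be filtered (with a recorded
  count) before entry, mirroring how development cohorts are assembled.
* Separation handling (drop-and-log) keeps the estimator faithful but
  means a resample's model can omit a predictor that is decisive in
  the full data; with 60-ish events this is rare but visible in the
  per-resample log.
* The grouped-data tools assume the integer score is the only
  predictor; they do not evaluate the underlying multivariable model,
  which requires patient-level data.
* `auc_pvalue()` uses the no-ties null variance with a continuity
  correction; with heavy ties it is conservative. It exists to
  reproduce the screening-stage p-values of cut-point reports, not for
  confirmatory inference.
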