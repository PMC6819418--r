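---
title: "Methods: decision-analytic evaluation of treatment-position prediction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-analytic evaluation of treatment-position prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem

In left-sided breast radiotherapy the heart — and above all the left anterior
descending coronary artery (LAD) — can receive a clinically meaningful dose.
For some patients the prone position spares the LAD; for others the supine
position does. The reference ("gold standard") way to decide is to acquire CT
series and full treatment plans in *both* positions and compare the planned
LAD mean doses, which is expensive and delivers extra imaging dose. The
package evaluates cheap surrogates: regression models that predict the
preferable position from four easily measured characteristics — BMI (kg/m²),
the in-field heart area on a single mid-heart supine CT slice, `a_heart`
(cm²), the median LAD–chest-wall distance `d_median` (mm), and the planning
target volume `ptv` (cm³, a proxy for breast size).

The dependent quantity is the **LAD mean dose difference**

$$\Delta = \bar D_\text{LAD}^\text{supine} - \bar D_\text{LAD}^\text{prone}
\quad (\text{Gy}),$$

with `label = 1` (supine preferred) when $\Delta < 0$ and `label = 0` (prone
preferred) when $\Delta > 0$. An exact tie ($\Delta = 0$) carries no
dosimetric preference; the package labels it 0 (prone) deterministically.
Ties have probability zero under the continuous generator, so the rule only
pins down reproducibility, and the antisymmetry of the labelling under
swapping the two positions (tested) holds everywhere else.

## Candidate models

* **Univariate logistic** models, one per predictor — used to show that no
  single measurement suffices, and to attach a probability (hence a Brier
  score) to each predictor.
* **Main-effect logistic**: `label ~ a_heart + bmi + d_median`.
* **Interaction-only logistic**: `label ~ a_heart:bmi + a_heart:d_median`
  with no main effects — the non-hierarchical form that forward
  likelihood-ratio selection can produce when products are on the candidate
  list.
* **Linear dose regression**: `dose_diff ~ a_heart + bmi + d_median` by OLS.
  Its decision is the *sign* of the predicted dose difference, so a patient
  predicted at −4 Gy weighs more in fitting than one at −0.2 Gy, and the
  model additionally estimates *how much* is at stake.

Stepwise selection (`stepwise_logistic()`) follows the SPSS likelihood-ratio
procedure: each step compares nested deviances on one degree of freedom;
forward entry requires `p < p_enter` (default 0.05), backward removal
requires `p > p_remove` (default 0.10). The defaults are the SPSS defaults;
both thresholds are exposed because the sensible choice depends on how many
pure-noise candidates are in play (see *Numerical choices*).

Before selection, `cluster_predictors()` screens for multicollinearity by
agglomerative clustering with distance $1 - |r|$ (Pearson) and average
linkage. Absolute correlation is used because collinearity is harmful
regardless of sign; the merge history is returned so the analyst can choose
poorly correlated predictors rather than having a cut imposed.

## Evaluation machinery

**ROC/AUC.** The AUC is the tie-corrected Mann–Whitney statistic computed
from midranks; its confidence interval uses DeLong's placement-value
variance. A brute-force $O(n^2)$ pair count and the pROC package serve as
independent cross-checks in the test suite.

**Youden cut-point.** Exhaustive scan over the midpoints between adjacent
distinct scores plus $\pm\infty$ sentinels; ties are broken toward the
higher threshold (higher specificity). Positive calls are made at
`score >= threshold` everywhere in the package, including net benefit.

**Brier score.** $BS = N^{-1}\sum_i (p_i - o_i)^2$, and the weighted form
$wBS = \sum_i w_i (p_i - o_i)^2 / \sum_i w_i$. Probabilities refer to class
1 (supine preferred). Which weights are clinically right is left to the
user — `|dose_diff|` is a natural choice, weighting each forecast error by
the dose at stake — so `weights` is an argument, not a baked-in convention.
Constant weights short-circuit to the unweighted mean so the two coincide
exactly, not merely to rounding.

**Net benefit and decision curves.** Peirce's benefit of a rule is
$B = (p\cdot TP - l\cdot FP)/N$ for profit $p$ and loss $l$; since neither
is measurable in this setting, the loss-to-profit ratio is taken as the odds
of the threshold probability $p_t$, giving

$$NB(p_t) = \frac{TP}{N} - \frac{p_t}{1-p_t}\,\frac{FP}{N}.$$

A decision curve plots $NB$ against $p_t$ with two references: treat-none
($NB \equiv 0$) and treat-all ($NB = \pi - \frac{p_t}{1-p_t}(1-\pi)$ for
prevalence $\pi$, which crosses zero exactly at $p_t = \pi$). The default
grid is 0.01–0.99 in steps of 0.01, which nests the coarser 0.1-step grid
typical of published tables; $p_t = 1$ is excluded because the odds diverge.

The linear model needs a reading on the probability axis: by default it
enters the curve as the fixed sign-rule classifier it is — its calls do not
change with $p_t$, and its curve varies only through the odds weighting of
false positives. This is the only rendering that requires no machinery
beyond the published decision rule. `calibrate_linear_model()` offers the
alternative interpretation (a univariate logistic of the label on the
predicted dose difference, thresholded like any other probability model),
clearly flagged as an interpretation layer.

**Bootstrap bands.** `bootstrap_nb_ci()` fits the model once, then resamples
(probability, label) pairs with replacement and recomputes $NB$ by
definition per resample; the 2.5th/97.5th type-7 (linearly interpolated)
percentiles form the band, matching spreadsheet PERCENTILE conventions.
Holding the model fixed mirrors how such bands are computed when resampling
is done outside the fitting software; `refit = TRUE` adds model-fitting
variability, and `size` lets the resample size differ from the fitted
cohort's size. In a nested simulation (200 cohorts of n = 138, 500
resamples each, truth from a 100 000-patient cohort — run as part of the
test suite) the fixed-model band's empirical coverage at $p_t = 0.3$ falls
within the 90–99% window around its nominal 95%.

**Repeated data splitting.** `repeated_split_validation()` draws simple
random 70/30 splits (test size `round(0.3 n)`; on n = 138 that is 41
held-out patients), refits the chosen model on each training part and
scores its decisions on the held-out part. Splits are not stratified —
single-class *training* draws, which can defeat a logistic refit, are
redrawn and counted rather than failed, since small cohorts make them a
routine event rather than an error. Beyond sensitivity/specificity/accuracy
the procedure pools `|dose_diff|` over misclassified held-out patients: a
wrong call on a 0.2 Gy patient and on a 6 Gy patient are very different
clinical events, and the dose distribution of errors is the honest summary
of that. Both the mean of per-repetition metrics and the pooled-count
metrics are reported, because the two aggregations differ when held-out
class counts vary across splits.

## The synthetic cohort generator

The clinical dataset behind this methodology is not public, so
`generate_cohort()` provides virtual cohorts with the statistical structure
the analysis assumes:

* Covariates `(bmi, a_heart, d_median, ptv)` from a multivariate normal,
  truncated at physical lower bounds by rejection sampling (rejection is a
  few percent at the defaults). Means (27 kg/m², 9 cm², 25 mm, 900 cm³) and
  SDs (4.5, 5, 9, 280) are plausible for a breast-radiotherapy population;
  the correlation structure makes heavier patients have larger breasts
  (BMI–PTV 0.60) and more in-field heart (BMI–A_heart 0.35), and puts the
  LAD closer to the chest wall when more heart is in the field
  (A_heart–d_median −0.45).
* The structural equation
  `dose_diff = -3.66 + 0.104*bmi + 0.218*a_heart - 0.0644*d_median + ε`,
  `ε ~ N(0, 1.05²)` Gy. Signs encode the accepted clinical directions:
  higher BMI and more in-field heart favour prone; a LAD far from the chest
  wall favours supine. The linear form reflects the finding that
  higher-order covariate terms add nothing for this outcome.
* PTV is *correlated but non-causal*: it never enters the structural
  equation, so its univariate discrimination arises purely through its
  correlation with BMI and A_heart — reproducing the observation that
  breast size alone is the weakest of the four predictors.
* `heart_diff` is a noisy linear rescaling of `dose_diff` (slope 0.4)
  calibrated to correlate at 0.87, emulating the strong heart–LAD dose
  relationship; it feeds no model.
* Per-position doses are back-filled: `lad_prone` truncated-normal
  (mean 6 Gy, SD 1.2, ≥ 0), `lad_supine = max(0, lad_prone + dose_diff)`,
  with the dose difference re-recorded after clipping so every record is
  internally consistent. The prone mean is set at the high end of typical
  prone LAD doses precisely so clipping is rare (~0.5%) and the re-recorded
  dose difference remains essentially linear in the covariates — otherwise
  the clipping rule itself would bias parameter-recovery checks.

The defaults were calibrated **once**, by simulation at n = 5000, to a
target pattern: univariate AUC ordering A_heart > d_median > BMI > PTV with
A_heart ≈ 0.855 and BMI ≈ 0.72, multivariate main-effect AUC ≈ 0.90, and
~60% supine-preferred prevalence (the level at which published
net-benefit magnitudes for this problem are reproduced). An earlier draft
left the BMI and PTV AUCs ~0.01 apart, which made their ordering a coin
toss at n = 5000; PTV's correlations were reduced to the frozen values
above so that all four univariate AUCs are separated by several times
their sampling error. PTV's resulting marginal AUC (~0.67) is somewhat
below published single-centre values (~0.72); keeping it higher would
crowd the BMI ordering, and nothing downstream depends on PTV's absolute
discrimination.

**What the generator does not emulate:** measurement error in the CT-derived
quantities, non-Gaussian covariate tails (truncation aside), heteroscedastic
dose noise, centre effects, or any nonlinearity in the covariate–dose
relationship. Tests passing on these cohorts therefore certify the
*machinery* — fitting, metrics, resampling, decision analysis — under the
stated assumptions, not the clinical transportability of any fitted
coefficients. Generator defaults must not be read as estimates of any real
cohort's regression coefficients.

## Numerical choices

* **Tie rules.** Gold-standard label at $\Delta = 0$ → prone; linear-model
  decision at prediction 0 → prone (the same rule applied to the predicted
  value); Youden ties → higher threshold; positive calls at
  `score >= threshold` throughout.
* **Separation.** Logistic fits with any standardized slope beyond 15 are
  flagged and shrunk to that cap, with the intercept re-optimized at fixed
  slopes. Probabilities stay strictly inside (0, 1), so resampling loops
  survive separated resamples instead of dying on a divergent fit.
* **Stepwise thresholds.** Defaults 0.05/0.10 (SPSS). Note that with $k$
  pure-noise candidates, forward selection falsely admits at least one with
  probability $1-(1-p_\text{enter})^k$ per sweep (~14% for $k=3$ at 0.05);
  exact-recovery experiments in the test suite therefore use a strict
  entry threshold (0.005), under which exact recovery of a single strong
  predictor is the expected outcome rather than an ~86% event.
* **Percentiles** are type-7 throughout (R's default, PERCENTILE-compatible).
* **Seeds.** Every stochastic routine takes a seed; `reproduce_study()`
  spawns per-stage seeds from one global seed (recorded in its manifest) so
  any stage can be reproduced in isolation. All spawned seeds stay below
  2³¹.
* **Problem sizes.** Calibration-sensitive checks run at n = 5000 (AUC
  sampling error ~0.007); coefficient recovery uses 20 seeds at n = 5000;
  bootstrap-coverage uses 200 nested simulations of n = 138 with 500
  resamples; split validation uses 1000 repetitions at n = 138. These sizes
  keep Monte-Carlo error well inside the tolerances being asserted.

## Known limitations

* The generator's truncated-Gaussian, homoscedastic, exactly linear world is
  friendlier than clinical data; external validity of any particular fitted
  model is out of scope by design.
* The heart-dose channel is a calibration target only; the secondary
  heart-dose decision algorithm used in some clinics is not implemented.
* Decision-curve profit/loss are handled exclusively through the
  threshold-probability odds; measured utilities are out of scope.
* DICOM-RT dosimetry, CT feature extraction and treatment planning are out
  of scope — the package starts from the measured covariate table.
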