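---
title: "Methods: temperature-corrected blood gases, seasonal reference intervals and predictor models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature-corrected blood gases, seasonal reference intervals and predictor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectogas)
```

`ectogas` packages the analysis chain used in wildlife clinical-pathology
field studies of ectotherm blood gases: point-of-care panels measured at
37 °C are corrected to the animal's environmental temperature, seasonal
reference intervals are constructed with outlier screening and bootstrap
precision assessment, and candidate linear models of physiologic and
environmental predictors are ranked by small-sample-corrected AIC. This
vignette is the package's own account of the science: the models, their
assumptions, the tunable parameters, the numerical choices, and what the
validation suite does and does not establish.

## 1. Temperature correction

Handheld analyzers (such as the iSTAT) warm blood to 37 °C. In a closed
sample, warming shifts pH down, pO₂ and pCO₂ up, so the readout must be
mapped back to the animal's temperature `T_A` — by convention here the mean
daily air temperature, though `correct_panel()` accepts any temperature
column, so cloacal or shell temperatures can be substituted when measured.

The correction set combines the analyzer's built-in human-derived
corrections for pH and pCO₂, a pO₂ correction from the sea-turtle
literature, and sea-turtle-derived equations for the CO₂ solubility
coefficient αCO₂ and the apparent carbonic-acid pKa. Bicarbonate and total
CO₂ are then *recomputed* through Henderson–Hasselbalch:

$$\mathrm{HCO_3^-} = \alpha_{CO_2}\, p\mathrm{CO}_2 \, 10^{\,\mathrm{pH} - pK_a},
\qquad
\mathrm{TCO_2} = \mathrm{HCO_3^-} + \alpha_{CO_2}\, p\mathrm{CO}_2 .$$

Two identities therefore hold *by construction* and are enforced by tests:
`tco2_c − hco3_c = alpha_co2 × pco2_c`, and
`log10(hco3_c / (alpha_co2 × pco2_c)) = ph_c − pka`.

Design notes:

* **pKa log-term grouping.** The pKa expression subtracts a log₁₀ term whose
  printed form is typographically flattened in the sources that state it.
  We implement it as the dimensionless quotient

  $$pK_a = P(T_A) -
  \log_{10}\frac{1.011 + 10^{\,\mathrm{pH} + 0.011\,T_A - 10.241}}
                {1 + 10^{\,\mathrm{pH} + 0.001\,T_A - 8.889}},$$

  the only grouping of the printed tokens that yields a dimensionless
  argument and physiologic pKa values (5.8–6.5 over pH 6.8–8.0 and
  5–40 °C). The quotient lives in its own exported function,
  `pka_log_quotient()`, so it can be swapped if a different reading is ever
  preferred. "log" is log₁₀ throughout, matching the Henderson–Hasselbalch
  convention and every other exponential in the set.
* **pO₂ exponent sign.** The correction is implemented exactly as published:
  corrected pO₂ *rises* as temperature falls below 37 °C. We do not
  "fix" the sign.
* **Base excess** is a function of bicarbonate, pH and hemoglobin; without a
  hemoglobin measurement it cannot be recomputed, so the analyzer value is
  passed through unchanged. Lactate is temperature-independent.
* **Validation windows, not gates.** Inputs outside the physiologic windows
  (pH ∈ (0, 14), temperature ∈ [−10, 45] °C) raise warnings, not errors —
  field data contain genuine extremes. Only non-finite values are rejected.
  Missingness propagates: a corrected field is `NA` exactly when an input it
  depends on is `NA` (analyzer cartridge errors are routine).

`invert_panel()` is the exact algebraic inverse (the pH correction is linear
in `pH_I`; the pressure corrections are multiplicative), used by the
simulator so that correction is exercised nontrivially; round-trips
reproduce panels to better than 1e−10.

## 2. Eligibility screening

Two screens mirror standard reference-population practice:

* `screen_health()` removes animals with *active* disease from the
  reference population (default codes: open-mouth breathing; ocular
  swelling / nasal discharge / diarrhea; necrotic shell fractures; oral
  plaques). Healed shell lesions and asymmetrical nares are deliberately
  retained — they are common, static findings in free-living chelonians.
  The code list is configuration, not ontology.
* `screen_multi_analyte_outliers()` excludes animals flagged by the Horn
  screen in ≥ 2 analytes from *both* reference intervals and modelling:
  multiple simultaneous outliers indicate a genuine pathologic acid–base
  disturbance rather than an isolated aberrant measurement. A single
  flagged value leaves the animal in; that value is still dropped
  per-analyte during interval construction.

Both screens are per-animal, hence idempotent and order-independent, and
every exclusion carries machine-readable reasons that the pipeline manifest
tallies.

## 3. Reference intervals

For each analyte × season, `build_reference_table()` performs, in order:

1. **Horn's outlier screen** (`horn_outliers()`): Box–Cox transform with λ
   chosen by maximum likelihood over the grid [−3, 3] step 0.05 (via the
   standard profile-likelihood machinery), then Tukey fences Q1 − 1.5 IQR /
   Q3 + 1.5 IQR on the transformed scale. Data containing values ≤ 0 (base
   excess) are shifted by 1 − min before transforming. The screen is a
   single pass; we note that with a gross outlier present the ML λ adapts
   to it, so occasionally a second borderline value crosses the fence with
   it — an inherent property of the one-pass method, visible in the tests.
2. **Descriptive statistics** (n, mean, SD, median, range) on the retained
   values.
3. **Distribution label**: Gaussian vs non-Gaussian by Shapiro–Wilk at
   α = 0.05; the Kolmogorov–Smirnov statistic (against a normal with the
   sample moments, no Lilliefors correction) is reported alongside but does
   not drive the label — one label per row, and Shapiro–Wilk is the
   stronger test at these sample sizes.
4. **Nonparametric 95% interval**: bounds at the rank index `p(n+1)` with
   linear interpolation, clamped to the observed extremes (R's type-6
   quantile). The clamping matters: at n ≈ 40 the 2.5th/97.5th bounds
   coincide with the sample minimum/maximum, which is exactly how such
   tables read in practice.
5. **Bootstrap 90% CIs** on each bound: percentile interval of the bound
   over 5000 with-replacement resamples (plain, unstratified), resampling
   the *post-outlier* data. Fully seeded; each analyte × season cell gets a
   deterministic sub-seed so single rows are reproducible in isolation.
6. **WCI/WRI**: CI width over interval width; a row is flagged imprecise
   when the larger of the two ratios exceeds 0.2, the conventional
   "collect more samples" threshold.

Cells with fewer than `min_n` values (default 20 — the field guidance
declines intervals in the high teens and computes them around 40) report
descriptive statistics with `computed = FALSE`.

Tunable parameters, with defaults: `coverage` 0.95, bound-CI `level` 0.90,
`reps` 5000, `min_n` 20, normality `alpha` 0.05, `wci_threshold` 0.2,
Tukey `k` 1.5, Box–Cox grid [−3, 3] × 0.05.

## 4. Candidate models, AICc and adjusted effects

Each corrected analyte is modelled by ordinary least squares. The default
candidate set has five members — Null, Activity, Season, PCV + Season,
Activity + PCV + Season — with season (three levels, reference spring) in
place of air temperature: the two are strongly correlated (the collinearity
screen flags |r| > 0.5) and season is antecedent to temperature in the
causal ordering. Activity is coded against "bright".

All candidates for one analyte share one complete-case dataset (rows missing
the response or *any* candidate predictor are dropped first), because AICc
comparisons are meaningless across differing data. `rank_models()` enforces
this. The parameter count `k` includes the residual variance, so the null
model has k = 2 and the full additive model k = 6; the Gaussian
log-likelihood is $-\tfrac{n}{2}(\ln 2\pi + \ln(RSS/n) + 1)$ and

$$AICc = -2\ln L + 2k + \frac{2k(k+1)}{n-k-1}, \qquad
w_i = \frac{e^{-\Delta_i/2}}{\sum_j e^{-\Delta_j/2}}.$$

Ties in AICc rank by smaller k. `p_overall` is the F-test of each fit
against the intercept-only model.

Effect estimation is separated from prediction: `adjusted_effect()` fits
the exposure plus its confounder adjustment set only (intervening variables
excluded). The default sets encode the assumed causal diagram — season is
antecedent to everything (unadjusted); temperature is confounded by season;
PCV by season and temperature; activity has no measured confounders — and
are plain configuration, since different populations may justify different
diagrams. `season_contrasts()` gives pairwise differences of model-adjusted
season means (covariates at sample means) with t-based inference and no
multiplicity adjustment by default, matching how single contrasts are
conventionally reported in this literature.

## 5. The synthetic-cohort generator

`sim_config()`/`generate_cohort()` emulate the field design the analysis
assumes, with defaults fixed once from the study conditions this kind of
survey reports:

* **Design**: 40/42/20 animals in spring/summer/fall; quiet-activity
  probability 0.673.
* **Environment**: season temperature means 19.0 / 24.47 / 16.65 °C with
  within-season SD 2.5 °C — chosen to reproduce reported pairwise seasonal
  differences (+5.47, +7.82, −2.34 °C) and an overall mean near 21 °C.
* **PCV (%)**: spring intercept 21.7, summer +7, fall +2.3, slope
  0.1 %/°C around 20 °C, residual SD 7. These imply a marginal SD near 8
  and a PCV–temperature correlation near 0.3 — under the 0.5 collinearity
  threshold, as observed in the field.
* **Analytes** are generated on the *corrected* scale as additive linear
  models in season, activity and PCV (centred at 25%) with Gaussian
  residuals — the same model family the analysis fits. Key effects: quiet
  pH −0.19, summer pH −0.13, fall pH +0.09; quiet pO₂ −9.3 mmHg; quiet
  pCO₂ +15 mmHg, summer pCO₂ +10, fall −7.5; summer lactate +2.36 mmol/l.
  Residual SDs (pH 0.11, pO₂ 17, pCO₂ 9, lactate 2.2) are backed out from
  field marginal SDs assuming top-model adjusted R² in the reported
  0.12–0.62 range; they are approximate, since residual SDs are never
  printed in such studies.
* **Derived analytes**: HCO₃⁻ and TCO₂ are *not* independently simulated —
  they follow from pH, pCO₂ and temperature through Henderson–Hasselbalch,
  so generated panels satisfy the corrected-panel identities exactly. Base
  excess is HCO₃⁻ − 24.8 plus Gaussian noise (SD 1): a crude surrogate that
  preserves the metabolic-axis correlation without inventing undisclosed
  device math. Consequently seasonal offsets for HCO₃⁻/TCO₂/BE are implied,
  not configured.
* **Instrument scale**: panels are mapped to 37 °C by exact inversion;
  instrument HCO₃⁻/TCO₂ are regenerated formula-consistently at 37 °C
  rather than imitating the analyzer's human-derived algorithm, which is
  not public.
* **Artifacts** (`inject_artifacts()`): per-field missingness (activity 4%,
  PCV 2%, BE 2%, lactate 1% — the rates implied by reported missing
  counts) and pathologic outliers in 3% of animals: ≥ 2 analytes displaced
  by 8 residual SDs in a coherent acidosis direction (pH and pO₂ down,
  pCO₂ and lactate up; a downward lactate shift would only hit the
  physiologic floor and mimic health). Floors keep displaced values
  physically representable. Lactate is floored at 0.1 mmol/l, pO₂/pCO₂ at
  1 mmHg, PCV clamped to (0, 60].

Everything is deterministic given the seed; the generator refuses to run
without one.

**What passing tests show — and don't.** The generator matches the
analysis's own assumptions (additivity, Gaussian residuals, independent
animals). Real panels have device-specific HCO₃⁻/TCO₂ algorithms, possible
lymph dilution, capture-stress drift, site structure and repeated-measures
correlation, none of which are simulated. Recovery of the generating
effects therefore validates the estimation chain, not the biology; field
reference intervals must still come from field data.

## 6. Numerical choices and degenerate inputs

* Quantiles: type 6 (`p(n+1)`) for interval bounds; the CI over bootstrap
  replicate bounds uses R's default type 7.
* Constant samples: Horn returns no outliers (fences collapse onto the
  constant); the reference interval is (c, c); the bootstrap CI is (c, c);
  a zero-width reference interval makes WCI/WRI `NaN` with a warning.
* Fewer than 3 values: no outlier screening (warning). Fewer than 8: no
  normality label. Below `min_n`: no interval.
* A saturated (zero-residual) fit has unbounded Gaussian likelihood;
  `fit_glm()` records `logLik = Inf` and `aicc()` errors when
  `n ≤ k + 1`, its own precondition.
* Rank-deficient designs error naming the aliased columns; fits over
  different complete-case sets cannot be ranked together.
* Report rounding follows conventional per-analyte precision: pH 2 dp,
  pO₂/TCO₂ integer, pCO₂/HCO₃⁻/BE 1 dp, lactate 2 dp.

## 7. Validation problem sizes

The test-suite simulations use sizes chosen to make each property's
Monte-Carlo error small relative to what it checks: round-trip and identity
checks over 10 000 random panels; estimator consistency at n = 10 000
(uniform draws, whose unit tail density makes the 0.02 tolerance
meaningful — the sampling SE of a Normal 2.5% quantile at that n is 0.027,
larger than the tolerance itself); bootstrap-CI coverage over 2000
simulated samples of n = 120 × 2000 resamples (the measured coverage,
91.8% ± 1.0 in a 3000-replicate calibration run, sits inside the 90 ± 3
band; mild over-coverage is characteristic of the percentile bootstrap for
tail-quantile bounds at this n); Horn sensitivity on 200 replicates of an
8-SD contaminant (flagged in 100%) and specificity on 200 clean samples
(≈ 0.8% of points flagged); and effect-size recovery over 100 cohorts of
400 animals per season, where the generating model ranks first in ≈ 100%
and the generating quiet-activity effects fall inside their 95% CIs at the
expected ≈ 95% rate.

## 8. Known limitations

* The correction constants are sea-turtle- and human-derived; no
  species-specific constants exist for most terrestrial chelonians, and the
  pO₂ correction's behavior below 37 °C follows the published source
  as printed.
* Horn's screen is one-pass by design; it does not iterate, and with ML
  Box–Cox it can be conservative against moderate (2–3 SD) outliers.
* No robust or parametric reference-interval variants, no partition
  justification testing, no mixed models or coefficient averaging, no
  diagnostic plotting beyond the `autoplot()` methods.
* The pipeline treats animals as independent; repeat captures are not
  modelled.
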