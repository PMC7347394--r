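---
title: "Methods: staged mortality models for VLBW neonates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged mortality models for VLBW neonates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlbwmort)
```

## The model family

`vlbwmort` implements a staged framework for predicting in-hospital
mortality of very low birth weight neonates (birth weight < 1500 g or
gestational age < 30 weeks) admitted to a NICU. All three models are
multiple logistic regressions on hospital mortality:

$$z = \beta_0 + \sum_j \beta_j x_j, \qquad
  P(\text{death}) = \frac{1}{1 + e^{-z}},$$

with survival probability reported as the complement. The stages differ
only in the information set:

* **M1 (prenatal):** gestational age (decimal weeks), antenatal steroids
  (none / partial / full, reference "none"), weight below the 10th
  centile, sex, multiple pregnancy, level of care (indicator for level 2).
* **M2 (24 h of life):** M1 variables plus birth weight (entered as
  g/100), Apgar at 5 min (integer 0–10), maternal hypertension, advanced
  resuscitation (intubation, chest compressions or adrenaline), admission
  temperature (°C), and severe respiratory distress syndrome.
* **M3 (during admission, dynamic):** two sub-models, applied on days
  1–30 and from day 31 onwards, both containing *days of life* as a
  numeric covariate together with perinatal variables and in-stay
  diagnoses/severity flags. Boundary convention: day 30 belongs to the
  early sub-model.

The shipped coefficients, standard errors and the printed odds
ratios/CIs live in `inst/extdata/published_models.json` and are loaded by
`published_model()`; derived (refitted) models use the same spec format
and the same scoring path, so nothing about the published equations is
hard-coded in logic.

A note on the shipped constants: for one coefficient (M1 level of care)
the printed odds ratio is not `exp(β)` of the printed coefficient, and
for several sparse rows the printed CI bounds are asymmetric around
`exp(β ± 1.96·SE)` in the way profile-likelihood intervals are. The
package treats the β/SE columns as authoritative; `odds_ratio()` is
strictly Wald (`exp(β)`, `exp(β ± 1.96·SE)`), and the acceptance test
pins both the agreeing cells (to ±0.005) and the exact set of
non-agreeing cells, so silent drift in the constants file is caught.

## Prognosis categories and FNR bands

Predicted probabilities are mapped to four categories — mild, moderate,
severe, very severe — corresponding to mortality bands of roughly 0–20%,
21–50%, 51–80% and 81–100%. The three boundaries per model were derived
with the false negative rate

$$\mathrm{FNR}(t) = \frac{\#\{\text{deaths with score} < t\}}
                         {\#\{\text{deaths}\}},$$

rather than predictive values, because deaths are rare and PPV-based
thresholds collapse toward zero. `derive_fnr_thresholds()` returns, for
each target level $q \in \{0.20, 0.50, 0.80\}$, the smallest *observed
death score* $t$ with $\mathrm{FNR}(t) \ge q$. Two decisions here are the
package's own:

* the numeric levels (0.20, 0.50, 0.80) mirror the four bands; the source
  does not state them, so the published boundaries are shipped verbatim
  rather than re-derived;
* the candidate grid is the set of death scores (not all scores), which
  makes the worked definition unambiguous and every threshold an attained
  score of a fatal case. Duplicate thresholds are perturbed to the next
  distinct death score and logged.

Band intervals are closed on the left band's side: a probability exactly
equal to a boundary belongs to the lower category. The source prints
bands like "0–0.158 / 0.159–0.368" without stating the convention; ours
is a decision, applied consistently in `categorize_risk()`.

## The pseudo-evolution expansion

Registry records are cumulative over the whole stay, so a day-dependent
model needs a reconstruction of the time course. `expand_pseudo_days()`
replicates each record over the standardized days
{1, 3, 8, 15, 22, 31, 46, 61}, keeping day $d$ only if $d \le$ length of
stay, and gates diagnoses outside their plausibility windows:
respiratory distress syndrome days 0–7, intraventricular hemorrhage days
0–10, necrotizing enterocolitis days 14–45, periventricular leukomalacia
after day 21, bronchopulmonary dysplasia after day 28. The outcome label
on every expanded row is the final hospital outcome.

Interpretation choices:

* **Deaths are truncated at the day of death**: rows require
  $d \le \min(\text{LOS}, \text{day of death})$, so the already-dead are
  never scored. The source does not state whether its expansion did this;
  we consider the alternative (scoring a patient on days after their
  death) clinically meaningless.
* **Severe flags obey the same window as their plain diagnosis.** A
  consequence worth knowing: severe intraventricular hemorrhage is
  structurally zero in the late stratum (its window ends at day 10), so
  when the dynamic model is *refit* on expanded data the late sub-model
  drops it as degenerate (logged). The published late equation still
  carries a severe-IVH coefficient — evidence that the original fit did
  not gate chronic severe flags this way — but the window rules as stated
  are applied uniformly; scoring with the published equation is
  unaffected for any patient whose gated flag is 0.
* **Open windows** ("after day 21/28") are encoded as inclusive
  `[start+1, Inf]`.

`fit_dynamic_model3()` routes rows at `days_of_life <= 30` to the early
fit and the rest to the late fit, with days of life kept as a numeric
covariate in both, and errors by name if a stratum is empty.

## Development procedure

* **Preselection** (`preselect_variables()`): chi-square (no continuity
  correction, small expected cells logged) for categorical candidates,
  Mann-Whitney U (normal approximation, tie correction) for continuous
  ones; keep if p < 0.15; constant variables are excluded with reason
  "degenerate".
* **Fitting** (`fit_logistic()`): maximum likelihood via `stats::glm`
  (binomial), complete cases with dropped-row counts recorded. Aliased
  columns are dropped and logged; separation is flagged (non-intercept
  |β| > 15 or fitted probabilities collapsed to 0/1 on both classes)
  rather than silently accepted. Intercept magnitude is deliberately not
  used as a separation signal: with gestational age in weeks, legitimate
  intercepts are ≈ 17.
* **Cutoffs** (`select_cutoff_max_kappa()`): the candidate grid is every
  unique score (exact optimum, computed in O(n log n) from cumulative
  counts), predicted death iff score ≥ cutoff, ties broken toward the
  smallest cutoff.

## Validation statistics

* **AUC**: Mann-Whitney form with half-credit for ties; CI by DeLong's
  placement-value variance (computed via midranks). The source reports
  CIs without naming a method; DeLong is the field default.
* **Brier score**: mean squared deviation; 0 perfect, 0.25
  non-informative.
* **Cohen kappa** with strength labels poor/weak/moderate/good/very good
  at boundaries 0.20/0.40/0.60/0.80 (boundary to the lower label;
  negative kappa is "poor"). If both classifications are constant and
  equal, kappa is defined as 1 with a warning.
* **Hosmer-Lemeshow**: g = 10 equal-frequency groups by default (the
  source is silent on g); tied quantiles collapse groups with a log
  message; p from chi-square with g − 2 df.
* **Nagelkerke R²** from model and null log-likelihoods.
* **Real-time scenario** (`real_time_scenario()`): for each day
  d ∈ {1, 8, 15, 31, 61}, subset to length of stay ≥ d, gate diagnoses at
  day d, score with the day-selected sub-model, report per-day AUC and
  the unweighted mean; a day with one outcome class is reported as
  undefined and excluded from the mean (logged).

## The synthetic cohort generator

The generator's defaults are the development-period description of the
registry: marginal prevalences of every binary/categorical field (e.g.
male 51.1%, RDS 64.0%, caesarean 71.1%), gestational age as a truncated
normal on [22, 34] weeks fitted to median 29.1 / IQR 27.2–30.8 (μ = the
median, σ = IQR/1.349; truncation shifts the realised median down by
≈ 0.1 w, accepted), birth weight linear in GA (slope 100 g/week, residual
SD 180 g, chosen to reproduce the published birth-weight median/IQR at
the GA distribution), death timing (18.5%, 65.3%, 16.2%) over
(<24 h, 24 h–30 d, >30 d), and an overall mortality target of 14.8%.

Outcomes are generated mechanically: a chosen `vlbw_model` (published M1
by default) produces $p_i$ and the outcome is Bernoulli($p_i$). With the
default covariates the uncalibrated published M1 yields mean
$p \approx 0.15$, already close to the registry's 14.8%; an optional
`calibrate = TRUE` shifts the intercept (by root finding) to hit the
target exactly. Calibration is off by default so that parameter-recovery
checks compare against the unmodified published coefficients.

Structure the generator does emulate: GA→birth-weight, GA→(RDS, IVH,
NEC) risk (logit-linear with slopes 0.35/0.30/0.25 per week, the
marginal recalibrated deterministically by root finding on the realised
GA vector so configured prevalences are met exactly in expectation),
resuscitation→Apgar, severe-implies-plain diagnosis logic (severe drawn
conditionally, with advanced resuscitation *derived* from the
resuscitation field and severe infection conditioned on any sepsis), and
survivor length of stay as 1 + negative binomial with mean
max(7·(36.5 − GA), 2) days (size 8) — i.e. discharge near 36–37 weeks
postmenstrual age.

Structure it deliberately does **not** emulate: any further joint
dependence (everything else is independent given GA), diagnosis onset
times (flags are stay-cumulative, exactly as in the registry extract),
competing risks between death timing and acquired morbidity, or
center-level clustering. A green test on this cohort therefore
establishes that the machinery is correct — scoring, expansion, fitting,
thresholding, statistics — not that the published models are valid on any
real population; the original validation results are not reproducible
without the registry, which is not publicly deposited.

Randomness: one root integer seed; each stage (covariates, diagnoses,
outcomes) re-seeds with a fixed affine derivation of the root, so
`generate_covariates()`, `assign_diagnoses()` and `simulate_outcome()`
are individually deterministic and the full pipeline is byte-identical
under a fixed seed. Generated `p_true` is rounded to 12 decimals so
cohort CSVs round-trip bitwise.

## Numerical and formatting conventions

* Gestational age is decimal weeks = weeks + days/7, rounded to 2
  decimals. The registry's footnote rounds a different way ("28 weeks and
  3 days = 28.5 w"); we treat that as presentation rounding and keep the
  exact convention.
* Probabilities print as percentages with one decimal (`as_percent()`),
  survival as 100 − mortality.
* When both plain and severe forms of a diagnosis appear in one equation
  (e.g. NEC and severe NEC in the late sub-model), the severe indicator is
  additive on top of the plain one: a severe case sets both flags.
* `death_probability()` refuses non-finite predictors; band constructors
  refuse non-increasing thresholds; scoring refuses a dynamic sub-model
  outside its day stratum and names any missing predictor.

## Known limitations

* The synthetic world is marginal-faithful but correlation-poor; measures
  of discrimination on it (AUC ≈ 0.86 for M1) are not estimates of the
  published real-data values.
* The refit dynamic late model cannot estimate effects of flags that the
  window rules null out (severe IVH), as discussed above.
* FNR band levels behind the published Table of cut points are not
  stated; derived bands will generally differ from the published ones.
* The Hosmer-Lemeshow statistic on expanded pseudo-day rows treats rows
  as independent, as the original procedure implicitly does; with many
  rows per patient its p-values are anti-conservative there.
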