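---
title: "Methods: a transdiagnostic early-warning score for psychiatric hospitalisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a transdiagnostic early-warning score for psychiatric hospitalisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psyews)
```

## The problem

Clinicians lack an early-warning score for mental-health deterioration of
the kind that is routine for physical health. `psyews` implements a
development-and-validation pipeline for such a score: a model of the
6-month risk of a first psychiatric hospitalisation built from repeated
clinician ratings of overall severity (CGI-S, 1–7) and functioning (GAF,
1–100), together with age, gender and seven non-exclusive diagnosis flags
(MDD, BD, GAD, PTSD, SCZ, ADHD, PD). Because the EHR data this methodology
targets are proprietary, the package ships a synthetic data generator with
a known ground-truth hazard, so every stage of the pipeline is exercised
and tested end to end on data whose right answer is known.

## Cohort and outcome

A patient enters the cohort if some closed 180-day window (the
*measurement period*) contains at least five CGI-S and five GAF ratings
and ends strictly before any hospitalisation. When several windows
qualify, the package takes the **earliest**, anchored at an observed visit
day: any qualifying window can be shifted left onto a visit day without
losing observations, so scanning visit-day starts is exhaustive and the
choice is reproducible. The outcome clock starts the day after the window
ends: a hospitalisation within the next 180 days is an event at that day;
otherwise the patient is censored at the last visit or at 180 days,
whichever comes first. Patients whose last visit falls inside the window
are retained with censoring time 0 (they contribute no risk time); one row
per patient.

## Predictors

Four metrics are derived from each window:

* **clinical severity** — the unweighted mean of CGI-S ratings;
* **functional severity** — the mean of inverted GAF, `100 − GAF`, so
  that higher values mean more impairment (0–99);
* **clinical / functional instability** — the time-adjusted root mean
  square of successive differences (tRMSSD) of the respective series.

The default tRMSSD is the root mean square of per-day rates of change,

$$\mathrm{tRMSSD} = \sqrt{\tfrac{1}{n-1}\textstyle\sum_{i=1}^{n-1}
\left(\frac{x_{i+1}-x_i}{t_{i+1}-t_i}\right)^{2}},$$

in score units per day. This is the natural "time-adjusted" form for
irregular visit schedules, and its magnitude is consistent with published
cohort medians (≈0.05 on the 1–7 scale, ≈0.24 on the inverted GAF scale,
with inter-visit gaps of days to weeks). The alternative that divides the
squared difference by the gap, $\sqrt{\mathrm{mean}(\Delta x^2/\Delta
t)}$ (units per √day), is available via `method = "sqrt_dt"`; the choice
is a configuration switch because the literature does not pin the formula
down. Same-day duplicate ratings are averaged before differencing, since a
zero gap is undefined under either form. Instability on raw versus
inverted GAF is identical (|Δ(100−g)| = |Δg|), which the tests assert.

Organisation-level propensity to hospitalise enters as a logit-transformed
hospitalisation rate with a continuity correction,
$\mathrm{logit}\big((e + 0.5)/(n + 1)\big)$, so that organisations with
zero events get a finite value. In external validation the rate is
computed from each validation organisation's own cohort outcomes — this
mirrors the adjustment's purpose (between-organisation differences in
propensity) but does use the validation outcome distribution; the package
documents this as the intended behaviour rather than leakage-free
prediction.

## Models

Four Cox proportional-hazards specifications are fitted on the derivation
split only: *unadjusted* (the four metrics + diagnosis + gender + age),
*adjusted* (+ the organisation logit rate), *baseline* (diagnosis, gender,
age) and *clinical benchmark* (baseline + clinical severity). Continuous
predictors are standardised with derivation-split constants that are
frozen into the model object; validation data is never standardised with
its own constants. Gender uses female as the reference with separate
male/unknown indicators. For each instability metric independently, a
square-root transform (applied before standardisation) is kept only if it
strictly lowers the AIC; ties keep the raw scale.

Fitting uses the partial likelihood with the Efron approximation for tied
event times — day-granular outcomes make ties routine — via the
`survival` package, with a hand-written partial-likelihood oracle in the
test suite guarding the route. Binary indicators whose minority level has
fewer than three patients (typically the handful of unknown-gender
records in a resample) are dropped before fitting as inestimable; constant
columns likewise, which also makes the adjusted model collapse exactly to
the unadjusted one when all organisation rates are equal. The 180-day
baseline survival $S_0(180)$ is stored from the Breslow-type cumulative
hazard at the all-zero covariate vector, so absolute risks are
$1 - S_0(180)^{\exp(\beta^\top x)}$. The proportional-hazards assumption
is checked with the Grambsch–Therneau scaled Schoenfeld score test on
untransformed time (the simplest reportable default; the
Kaplan–Meier transform remains available through `survival`).

## Validation

Discrimination is Harrell's c-index for right-censored data.
Internal validation uses the optimism-correction bootstrap (200
repetitions by default): each resample repeats **every** data-driven step,
including transform selection, so the correction covers the whole
modelling procedure; resamples without events are redrawn and logged.
External validation applies the frozen model to the held-out
organisations. Operating-point metrics flag the top 5% of predicted risk
(a single reported cut-off; configurable), and PPV/NPV are re-pinned by
Bayes' rule to a prespecified 2% incidence — the only reading under which
a *prespecified* incidence can enter predictive values. Calibration uses
ten equal-count risk bins with the observed risk taken as one minus the
Kaplan–Meier survival at 180 days within the bin (exactly the event
proportion when no one is censored) and within-bin bootstrap CIs. The
Brier score is the plain mean squared error against the binary 180-day
outcome, without censoring weights: in the intended setting follow-up is
nearly complete (median 180 of 180 days), so the unweighted form is
reported and an IPCW variant was deliberately left out of scope.
Transdiagnostic validity is assessed by evaluating the global model inside
each (non-exclusive) diagnostic subgroup; fairness by comparing c-indices
between white and non-white patients (unknown race excluded) with a
label-permutation test (add-one p-value, so 100 permutations can never
yield p = 0). Model comparisons use a patient-level paired bootstrap
(1000 repetitions) of the difference in c-index.

## Intervention impact

The impact module chains four pieces of arithmetic for an intervention
that multiplies the odds of hospitalisation by $(1-r)$ (e.g. a crisis
resolution team with $r = 0.8$): post-intervention risk from
pre-intervention risk, expected hospitalisations prevented among
`n` treated individuals whose risk equals the flagging strategy's PPV, the
number needed under a better-targeted strategy to match a prevention
target, and the implied resource saving. The reduction acts on the *odds*
scale — the risk-scale alternative does not reproduce the published
worked example — and the matching target is the headline (rounded)
prevention count of the benchmark strategy, which is what makes the
chained example land on 560 treated individuals and a 44% saving.

```{r impact}
impact_scenario(n_treated = 1000, ppv_benchmark = 0.054,
                ppv_model = 0.098, odds_reduction = 0.8)
```

## The synthetic generator

`simulate_dataset()` emulates the structure the analysis assumes: ~20
organisations with normally distributed baseline log-odds of
hospitalisation; patients with Table-1-like demographics and
non-exclusive diagnosis flags (redrawn until at least one is present);
visit days from a uniform counting process over 450 days thinned by a
geometric dropout; a latent severity path with patient-level mean
(standard normal) and stationary AR(1) deviations whose innovation SD is
drawn per patient — this is what makes instability a real, patient-varying
trait; CGI-S = clip(round(4 + s)) and GAF = clip(round(55 − 10·s + noise)),
each recorded with probability 0.85. The hazard is **constant within the
180-day outcome window** (exponential), the simplest shape compatible
with a proportional-hazards analysis, which makes the per-patient
180-day risk available in closed form, $1 - e^{-180\lambda_i}$, for
oracle tests. Crucially, the log-hazard acts on the *realised* features
computed from the emitted ratings through the same code path the analysis
uses — not on latent parameters — so Cox coefficient recovery is a
well-posed test. Events are kept only if they fall within 180 days of the
window end and before the patient's last visit (the censoring the
analysis applies), and are generated only for patients with a qualifying
window, since others cannot enter the cohort. Reproducibility comes from
one global seed feeding per-patient substreams keyed by patient index, so
generation order does not matter and a prefix of a larger cohort equals
the smaller cohort.

`preset_paperlike()` targets the published cohort's marginals: median
clinical severity ≈ 4, ≈57% female, 6-month incidence ≈ 1.4%. Its true
hazard ratios are 1.49/1.20/1.15/1.13 per SD of functional severity,
functional instability, clinical severity and clinical instability, plus
diagnosis effects (BD 1.53, SCZ 1.92, ADHD 0.47) and an organisation
log-odds SD of 0.4. The baseline 180-day risk is set to 0.010, *below*
the target marginal incidence, because positive covariate effects and
organisation spread inflate the marginal rate by roughly
$e^{\mathrm{Var}(lp)/2}$ ≈ 1.4; the simulated incidence lands near 1.6%.
What the generator does **not** emulate: diagnosis comorbidity structure,
medication, informative dropout, rater drift, or visit schedules that
react to deterioration. Passing tests therefore demonstrate that the
pipeline recovers a known data-generating process, not that the score
attains any particular performance on real EHR data.

## Numerical and design choices

* Dates are integer day offsets; all windows are whole-day arithmetic.
* The unknown-gender category is kept as its own indicator, dropped only
  when inestimable (< 3 patients in a level).
* `fit_scaling()` refuses zero-SD predictors by name; transform selection
  never sees a degenerate instability column because of this guard.
* Bootstrap CIs are percentile CIs; permutation and bootstrap p-values use
  add-one corrections; every resampling routine takes an explicit seed and
  is invariant to patient row order.
* Model files are JSON with 17-significant-digit numbers, so predictions
  are bit-identical after a save/load round trip.

## Problem sizes used in the checks

The package's heavier statistical checks run at sizes chosen to make
their conclusions stable while keeping a full test run comfortably
repeatable on a laptop: coefficient-recovery coverage over 100 replicate
simulations of 3000 patients (checked against a [90%, 99%] band for
nominally 95% CIs, with the organisation spread set to zero so the fitted
model is exactly the generating model — with a latent organisation
frailty the unadjusted model would be misspecified and per-SD
coefficients attenuated, a different question from estimator coverage);
optimism behaviour at n = 130 (overfitting detected, optimism > 0.05)
and at n = 10,000 with an event-rich, strong-signal design (optimism <
0.02); fairness type-I error over 500 replicate null datasets; calibration
of well-specified risks over 20 seeds; and a byte-identity check of two
full pipeline runs at n = 20,000.

## Known limitations

The generator's hazard is constant over the outcome window, so
non-proportionality and time-varying effects are exercised only through
purpose-built fixtures. The organisation adjustment in external validation
uses validation-cohort outcomes (see above). The Brier score is
unweighted. Recurrent admissions, voluntary/compulsory status and
dynamic (repeatedly updated) scores are out of scope, as are net-benefit
analysis and recalibration methods.
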