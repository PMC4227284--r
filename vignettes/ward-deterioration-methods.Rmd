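---
title: "Methods: severity scores, time windows and the nested case-control analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity scores, time windows and the nested case-control analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wardscores)
```

## The design

`wardscores` implements a retrospective nested case-control analysis of
clinical deterioration among ward patients admitted with infection. A
*case* is any admission with a qualifying event — ICU transfer, critical
care consult, rapid response evaluation, or in-hospital death — and its
*index time* is the earliest of these. For each case one *control* is drawn
by risk-set sampling from admissions that never had any qualifying event
and survived to discharge, matched on hospital admission date, with length
of stay exceeding the case's admission-to-index interval; the control's
index time is placed at the same offset from its own admission. This makes
the exposure window comparable within each pair.

Nine severity scores are then computed for every matched subject in four
pre-index windows (0–12, 12–24, 24–48, 48–72 hours), discrimination is
compared across scores and windows, and a two-threshold decision rule on
the earliest SOFA score and its change over time is derived and evaluated.

Two deliberate deviations from textbook incidence-density sampling are
documented here. First, classic risk-set sampling allows a future case to
serve as a control before its own event; the design implemented excludes
ever-cases outright, as the additional survival/no-event condition
requires. Second, date matching is exact by default but widens one day at a
time (to at most ±3 days) when no same-day candidate exists, so that
moderately sized synthetic cohorts do not shed pairs; set
`widen_to = 0` in `sample_controls()` for strict same-day matching.
Controls are used without replacement, matching a 1:1 design with distinct
controls. Ties among eligible controls are broken uniformly at random under
the sampling seed.

## The scoring engine

Each scoring system is described entirely by a JSON fixture: an ordered
table of half-open bands `[lo, hi)` mapping each physiologic component to
integer points, plus *special terms* — boolean flag items and named hooks
for the pieces that are not a one-dimensional band (the APACHE II GCS term
`15 − GCS`, its FiO2-dependent choice between A-aDO2 and PaO2 bands, the
SAPS II admission-type and chronic-disease points, the MEDS respiratory
distress trigger, the SCS consciousness ladder). Separating clinical
content from code keeps the tables auditable: every band in
`inst/extdata/scores/*.json` can be checked against the system's original
publication, which each fixture names in its `provenance` field.

The SOFA, APACHE II, SAPS II, MEWS, ViEWS and REMS tables are transcribed
from the widely reprinted originals. The PIRO (emergency-department variant
for suspected infection), SCS and MEDS fixtures are best-effort
transcriptions and are labelled as such in their provenance notes; their
fixtures document the assumed source publication. Scores are compared as
integer points only — no logit-to-probability calibration is applied.

Conventions that matter:

* **Half-open bands.** A value equal to a cut-point belongs to the band it
  opens. Fixtures encode cut-points as the source's ≥/≤ notation dictates.
  A value outside every band raises a configuration error — never silent
  clamping.
* **Ward context.** Patients are pre-ICU: `mechanical_ventilation` and
  `vasopressors` default to `FALSE`, so the SAPS II ventilated-PaO2/FiO2
  term and the SOFA vasopressor escalation are inert. The SOFA respiration
  bands are applied on PaO2/FiO2 alone, without the original's
  ventilatory-support requirement for 3–4 points, since the cohort is
  unventilated. Mean arterial pressure is derived as `(SBP + 2·DBP)/3`
  where not recorded. With no blood gas (most patients), oxygenation terms
  score from the normal-default PaO2 — the assume-normal rule.
* **Consciousness.** GCS is not charted; the AVPU level is converted to the
  near-equivalent GCS (A=15, V=13, P=8, U=3), a strictly monotone mapping.
* **Uncollected items score normal.** SCS functional-status items
  (breathless, unable to stand, abnormal ECG, new stroke) score 0 when the
  flag is absent; SAPS II urine output, never charted on the wards, scores
  from its normal default.
* **All-normal minimum.** `normal_snapshot()` (age 35, alert, room air, no
  flags, neutral scheduled-surgical admission type) scores the documented
  minimum of all nine systems — the anchor the test suite asserts. Cohort
  patients carry `admission_type = "medical"`, which adds the SAPS II
  medical-admission points by design.

## Windows, worst values and imputation

Observations land in the window whose half-open hours-before-index interval
contains them (a reading exactly 12 h before the index belongs to 12–24 h).
Within a window, the *worst* value of a component is the one earning the
most points under the score at hand; because two readings can earn equal
points, ties resolve first to the more deranged value (the signed extreme
for one-sided components, distance from the zero-point band's midpoint for
two-sided ones), then to the reading closest to the index. Components a
score consumes only through a hook (e.g. PaO2 for APACHE II oxygenation)
take the extreme on the deranged side declared in the normal-values
registry.

Missing cells are completed by a two-stage cascade. "The preceding
interval" is read as *earlier in clock time* — the window farther from the
index — for two reasons: carrying a value from nearer the index would leak
deterioration signal backward in time, and the farthest windows could never
be filled from admission-day measurements otherwise. The default policy
(`carry = "nearest"`) searches outward past empty windows for the nearest
*measured* value (carried values are never re-carried); `"one_step"`
restricts the search to the adjacent window. Anything still missing is
assumed normal, from the shared normal-values fixture. Every cell records
its provenance (`measured` / `carried` / `normal_default`). Whether the
original design carried vitals as well as laboratory values is not
determinable from its description; the cascade here treats both uniformly,
which the provenance column makes visible. Windows that predate admission
are flagged `in_hospital = FALSE`, filled with defaults for completeness,
and excluded from every downstream comparison.

## Evaluation

* **AUC.** Mann–Whitney concordance with ties counted ½; variance and 95%
  CI from DeLong's structural components; the paired DeLong test compares
  two scores on the same subjects; comparisons across unequal samples use
  the ad hoc z-statistic with an assumed correlation of 0.5. The package's
  own DeLong implementation is cross-checked in the test suite against an
  independent one (pROC) and against brute-force pair counting.
* **Thresholds.** Scores are integers, so the Youden-optimal threshold scan
  over observed values and the exhaustive grid over
  `(θ_base, θ_delta)` pairs are exact searches, not heuristics; both are
  verified against independent enumeration oracles. Ties go to the lowest
  threshold (lexicographically smallest pair), preferring the more
  sensitive rule.
* **The Δ-score rule.** Per subject, `earliest` is the score in the
  farthest-from-index in-hospital window, `current` the score in the 0–12 h
  window, `delta = current − earliest`, `peak` the maximum over in-hospital
  windows. A subject with data in a single window has `delta = 0` by
  construction and is classified by the base threshold alone. The rule is
  *positive ⇔ earliest ≥ θ_base OR delta > θ_delta*.
* **Odds ratios.** Crude ORs use the 2×2 cross-product with Woolf
  log-scale intervals; a zero cell triggers the Haldane–Anscombe 0.5
  correction, flagged in the output. In a balanced 1:1 analysis the crude
  OR equals `sens·spec / ((1−sens)(1−spec))` exactly — the identity the
  internal-consistency checks exploit. Adjusted ORs come from
  *unconditional* logistic regression on the rule indicator plus age, sex,
  severe sepsis, pneumonia and congestive heart failure; whether the
  original analysis conditioned on the matched pair is not stated, and the
  unconditional model is the conservative default for a rule evaluated on
  the pooled groups. Perfect separation raises an error; with
  `penalized = TRUE` a Firth bias-reduced fit (Jeffreys-prior score
  correction, implemented in-package) is used instead.
* **Trajectories.** A linear mixed model of the windowed score on group,
  window (categorical time, farthest window first), their interaction and
  the baseline covariates, with a patient-level random intercept; an
  intercept+slope structure is also fitted and the smaller-AIC structure
  (ML) kept. The candidate set is fixed to these two structures. Contrasts
  between consecutive windows within each group use Satterthwaite degrees
  of freedom (lme4/lmerTest).
* **Multiplicity.** None applied; p-values are reported raw with α = 0.05,
  matching the design being emulated.
* **Mortality endpoint.** The same code path with the endpoint as a
  parameter: cases are restricted to in-hospital deaths, each keeping its
  matched control.

## The synthetic cohort generator

No patient-level data accompany the design, so the generator is the
package's test bed: it reproduces the statistical *structure* the analysis
assumes, with known ground truth.

Defaults, fixed a priori as the study conditions: 5,188 admissions with
case probability 328/5188; time from admission to first event log-normal
with median 32 h and log-SD `log(124/12)/(2·Φ⁻¹(0.75)) ≈ 1.73`, chosen so
the quartiles sit near the 12 h and 124 h marks; control length of stay
log-normal (median 60 h, log-SD 0.8), which puts roughly 60% of stays
under 72 h; vitals charted 4-hourly with whole 12-h blocks missing at
probability 0.03; daily metabolic panels with 24-h blocks missing at
probability 0.06; blood gases in 30% of patients; event channels fired
independently at 142/328 (ICU transfer), 100/328 + 100/328 (consult, rapid
response) and 110/328 (death), conditioned on at least one, with death
closing the stay; comorbidity prevalences and demographics per arm follow
the baseline contrasts of the emulated design (severe sepsis 76% vs 32%,
pneumonia 42% vs 26%, CHF 38% vs 30%, age medians 67 vs 64, female 53% vs
63%).

Physiology is drawn around the documented normal midpoints in
`inst/extdata/normals.json` — the *same file* the imputation cascade uses,
so simulator and imputer can never disagree about "normal". Case values
drift linearly toward the deranged side (direction declared per analyte)
from 48 h before the event, at 0.5 baseline SD per 12 h; per-component
effect sizes are not estimable from the emulated design's report, so this
is a package choice, selected once as a moderate effect and not tuned.
AVPU is a deterministic step function of the latent drift (alert below
1.2 SD, then V/P/U), and supplemental oxygen is charted when the drawn
saturation dips below 92%.

What the generator does **not** emulate: cross-analyte correlation beyond
the shared drift (real labs co-move), measurement batching and clinician-
triggered sampling (sicker patients are measured more often in reality —
here missingness is independent of severity), interventions and treatment
feedback, multi-admission patients, and pediatric physiology. Passing tests
therefore demonstrate that the *machinery* — scoring, windowing,
imputation, matching, estimation — behaves correctly under a known
generating process, not that any real cohort would reproduce specific AUC
values. Simulated discrimination is in fact stronger than a real ward
cohort's, because the drift is clean and monotone.

## Problem sizes and numerical choices in the test suite

The simulation-property checks use cohorts of 650 admissions over 20 seeds
(the qualitative claims: near-event AUC exceeds far-from-event AUC for
every system; the mixed model detects the rising case trajectory; the
Youden index of the Δ-rule is at least that of the peak model, which is at
least that of the earliest model, in expectation). Null calibration uses
500 AUC replicates at 50 cases/50 controls and 200 mixed-model replicates
at 80 subjects for the consecutive-contrast type-I error. These sizes are
the package's choice of a desk-scale experiment with stable averages.

Remaining numerics: band tables are validated at load (no gaps, no
overlaps); generated values are truncated to physiologic plausibility
ranges; thresholds scan observed integer values only; the delta-rule grid
extends one step past the observed extremes so either arm can be switched
off; duplicate-control use is prevented by sampling without replacement;
and all randomness flows from explicit integer seeds, so identical
parameters give byte-identical cohorts.

## Known limitations

The PIRO/SCS/MEDS band fixtures are assumed-source transcriptions (see
above). The APACHE II chronic-health term is driven by a single
organ-insufficiency flag rather than full chart criteria. The generator's
effect sizes are free parameters. Conditional (matched-pair) logistic
regression for the adjusted OR is not implemented; the unconditional model
is the only route. And the mixed-model AIC selection compares two random
structures only — richer covariance families are out of scope.
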