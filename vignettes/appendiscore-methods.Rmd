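---
title: "Methods: scoring rules, accuracy auditing and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring rules, accuracy auditing and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(appendiscore)
```

This vignette is the package's own account of its methods: the three
clinical decision rules and the places where their published weight tables
are ambiguous, the diagnostic-accuracy machinery, the confusion-matrix
reconstruction/audit engine, and the synthetic-cohort generator with its
calibration. Everything quantitative stated here is computed by the test
suite or by `scripts/acceptance.R`; nothing is asserted from memory.

## The three scoring rules

All three rules are additive tables of item weights over symptoms, signs
and laboratory values, evaluated against the histopathology gold standard
(`histo_positive()` treats acutely inflamed, gangrenous and perforated
specimens as disease-positive; a `negative` specimen is a negative
appendectomy).

Published weight tables leave several thresholds implicit, and a faithful
implementation has to make them explicit. The choices below are defaults of
`scoring_config()` and every one of them is configurable:

- **Alvarado implicit thresholds.** "Elevated temperature", "leukocytosis"
  and "shift to the left" carry no numbers in the table; we adopt the
  classical definitions T ≥ 37.3 °C, WBC ≥ 10×10⁹/L and PMN ≥ 75 %. RIPASA's
  "leukocytosis" uses the same WBC ≥ 10×10⁹/L.
- **AIR band edges.** The printed PMN bands "70–84 %" / "> 85 %" and WBC
  bands "10–14.9" / "> 15.0" leave 84–85 and 14.9–15.0 unmapped; we use the
  half-open bands [70, 85) → 1, [85, ∞) → 2 and [10, 15) → 1, [15, ∞) → 2,
  and likewise CRP [1, 5) → 1, [5, ∞) → 2, so the bands partition the axis.
- **AIR peritonism** is one mutually exclusive graded item: muscular defence
  medium (2) or strong (3) dominates; light guarding or rebound tenderness
  scores 1.
- **AIR risk bands.** The printed footnote enumerates 1–4, 5–7 and 9–12,
  leaving score 8 unmapped. The original AIR rule places 8 in the
  intermediate band, so we implement low 0–4, suspected 5–8, high 9–12 —
  documented here rather than warned about at run time, since the gap is a
  property of the printed table, not of any particular call.
- **RIPASA fever** is the open interval (37, 39) °C: a patient at exactly
  37 or 39 °C scores nothing, and warming a febrile patient past 39 °C
  removes exactly the 1.0 fever point. This is the one deliberately
  non-monotone item, and the band edges are asserted exactly in the tests.
- **RIPASA duration at exactly 48 h** takes the ≥ 48 h weight (0.5): ties go
  to the longer-duration, lower-weight side.
- **RIPASA guarding** has a single weight (2.0) for any grade ≥ light,
  unlike AIR's graded item.
- **Cutoff semantics.** The study cutoffs are "> 7", "> 5" and "> 7.5".
  For the integer-valued Alvarado and AIR, strictly-greater is unambiguous
  (≥ 8 and ≥ 6). For RIPASA, 7.5 itself opens the printed high-probability
  band "7.5–11.5", so the call is score ≥ 7.5. Strictness is a config
  switch per system.
- **RIPASA bands.** unlikely < 5, low 5–7, high 7.5–11.5, diagnosis ≥ 12:
  scores live on a 0.5 lattice, so these partition every reachable value
  (the printed footnote's 11.5–12 gap is closed upward).
- **The printed RIPASA total of 17.5** is not reachable: the three mandatory
  mutually exclusive categories (sex, age, duration) contribute at most
  1.0 + 1.0 + 1.0, giving a reachable maximum of 16.0 and minimum of 1.5.
  The acceptance script confirms 16.0 by scoring a maximal patient.
- **Missing data are a hard error** naming the field and record; a decision
  rule evaluated on silently imputed items would corrupt any downstream
  accuracy estimate.

## Diagnostic accuracy

`diagnostic_metrics()` returns all eight summary metrics at full precision;
`round_metrics()` applies display rounding (half-up, one decimal for
percentages, two for ratios, three for AUC) and is the *only* place rounding
happens. Metrics with empty denominators (PPV with no positive calls, PLR at
specificity 1, NLR at specificity 0) are returned as `NA` and named in an
`undefined` attribute rather than becoming silent infinities.

Base R rounds half-to-even; published clinical tables round half away from
zero, so the display dialect is implemented as `round_half_up()` (with
half-even available everywhere as a sensitivity switch for the audit). A
guard of 10⁻⁹ absorbs binary representation error in rationals such as
114/132 × 100; no quantity in this domain is genuinely that close to a
rounding boundary.

`roc_auc()` sweeps every distinct score as a threshold and integrates by
the trapezoid rule; tied scores produce diagonal segments, which makes the
area identical to the Mann–Whitney pair count with ties weighted ½. This
equivalence is asserted exhaustively over every label configuration at
n ≤ 6 on a heavily tied alphabet, and on random tied instances up to
n = 12, and the implementation is cross-checked against `pROC` on a larger
instance. Invariance under strictly monotone transforms is property-tested.

`auc_difference()` reports the paired AUC delta with an optional seeded
bootstrap percentile interval (default 2,000 resamples in the analysis
scripts), stratified by disease class so every resample contains both
classes. This interval is this package's own significance machinery; the
comparable published comparison reported a p-value by an unstated method,
which we make no attempt to reproduce. Pearson correlations go through
`stats::cor` after explicit validation.

## Reconstruction and audit of published rows

A published accuracy row prints rounded metrics, but the underlying 2×2
cells are integers on known marginals. `reconstruct_matrix()` tests every
tp ∈ 0..n₊ and tn ∈ 0..n₋ — at most 122 × 12 candidates on the shipped
marginals, milliseconds of work — and keeps the matrices whose sensitivity
and specificity round to the printed values at their printed precision. The
printed precision is inferred from the value itself (25 → integer, 33.3 →
one decimal, 78.03 → two), so each cell is matched at its own display
precision. An empty candidate set is an explicit "impossible row" error;
several candidates flag non-uniqueness.

`audit_row()` then recomputes every further printed cell from each candidate
and issues a per-cell verdict: `match` at display precision, `near-miss(d)`
when off by at most one unit in the last printed digit, `impossible`
otherwise. Two recurring ambiguities of published tables are reported
rather than adjudicated:

- some cells are *truncated* rather than rounded; the audit reports
  `matches_truncated` per cell;
- likelihood ratios are sometimes derived from the display-rounded
  sensitivity/specificity rather than from the raw counts; the audit
  reports that derivation too (`from_rounded`).

On the three shipped rows the engine recovers a unique matrix each —
(107, 4, 14, 7), (94, 2, 27, 9), (117, 3, 4, 8) — and finds every printed
PPV/NPV/NLR cell an exact match. Three cells illustrate the ambiguities:
two accuracy cells (86.3 printed vs 86.36 computed; 94.6 vs 94.70) are
one-unit near-misses exactly consistent with truncation, and one PLR cell
(printed 3.54) reproduces exactly only as 96.7/(100−72.7) from the rounded
percentages, the from-matrix value being 3.5455 → 3.55. The audit keeps the
from-matrix computation as the primary verdict and reports the alternative
derivation alongside, because deciding the original authors' arithmetic is
not the audit's job.

## The synthetic cohort generator

No patient-level data are available, so `generate_cohort()` provides a
seeded stand-in with the statistical structure the analysis needs: the
histopathology label is drawn first (prevalence 121/132; histology mix
92/4/25 among positives), and every clinical feature is drawn conditional on
the label. Labs are truncated normals or log-normals on clinically
plausible ranges (WBC on [2, 30]×10⁹/L, temperature on [35, 41] °C, PMN on
[40, 99] %, CRP and duration log-normal), and the scoring rules threshold
the raw values — the scorer consumes exactly the fields a real cohort CSV
would carry. Every variate is drawn through a fixed-length inverse-CDF
stream, so a seed determines the cohort bit-for-bit regardless of how
parameters partition the patients.

Design choices where the design was genuinely open:

- **Conditional independence given the label** is the baseline assumption —
  no joint feature distribution has been published, so independence is the
  minimal structure. Because purely independent items under-disperse the
  scores, an optional shared latent severity is provided: a standard-normal
  draw per patient enters every flag's logit (loading 0.9 by default) and
  every lab's mean (0.6 SD per unit). The defaults switch it on, which both
  widens the score distributions enough to hold the published score means
  (8.14 / 7.69 / 11.68, all within the ±1.5 soft band at the calibrated
  defaults) and induces positive score–score correlation, unattainable
  under pure independence at this prevalence.
- **Sex and age are class-conditional.** Negative appendectomies are
  reported to skew towards women of reproductive age, and that skew turns
  out to be structurally necessary: an Alvarado-positive negative patient
  (≥ 8 of 10) shares so many items with RIPASA that only the demographic
  items (female 0.5, age ≥ 40 0.5, duration ≥ 48 h 0.5, no RIF pain) can
  keep her under the RIPASA 7.5 cutoff. The positive-class sex/age are
  pinned so the cohort-level marginals stay at the published 79:53 male
  ratio and age 24 ± 11.6 on [9, 70].
- **Calibration.** `calibrate_cohort_params()` runs a seeded coordinate
  search over the class-conditional flag probabilities, guarding
  log-weights and lab locations, minimising the squared deviation of
  Monte-Carlo sensitivity/specificity (20,000 patients per evaluation,
  common random numbers across candidates) from the target operating
  points. It was run once, against the shipped published operating points,
  and the result is frozen as the `cohort_params()` defaults; the
  calibration machinery remains exported and tested. At the frozen
  defaults, all six operating points sit within 5 percentage points of
  their targets on independent 20,000-patient cohorts (the acceptance test
  asserts exactly this); the hardest case is RIPASA sensitivity, which
  stays ≈ 2 points above its 96.7 % target because the published operating
  point implies a heavier left tail among disease-positive RIPASA scores
  than any additive-item model of this form produces.
- Feature-level marginals were never published, so the calibrated
  probabilities are **one consistent choice, not an estimate** of the study
  population: many parameter sets reproduce the same operating points.

What passing tests do and do not show: they show the pipeline is correct
and that cohorts with the published label structure and operating
characteristics flow through it end to end; they do not show that any real
population's feature joint distribution looks like the generator's. In
particular the generator's AUCs are higher than the published ones — its
conditional distributions are cleaner than clinical reality — and no
acceptance claim rests on reproducing real-cohort AUCs or correlations.

## Problem sizes and seeds

The default generator seed is 20220101; the analysis scripts and fixtures
derive from it, and every stochastic function takes an explicit seed.
Tests use cohorts of 500–20,000 patients (20,000 where an operating point
is measured, keeping Monte-Carlo error near ½ point on sensitivities);
`scripts/acceptance.R` uses 20,000 simulated patients and takes its seed
from the command line. The reconstruction engine is exact and needs no
sampling.

## Known limitations

- The generator models presentation-time features only: no time-to-surgery,
  complications or length of stay, and no imaging features (the emulated
  study used none).
- The audit reconstructs from sensitivity/specificity only; reconstruction
  from a printed AUC is impossible without the full score distributions and
  is deliberately out of scope, as are DeLong tests, calibration curves and
  decision-curve analysis.
- Wilson or bootstrap intervals for the Table-style metrics are not
  reported by default (the emulated study reports none); the AUC-difference
  bootstrap is the only interval machinery.
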