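---
title: "Warning-score triage and diagnostic accuracy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Warning-score triage and diagnostic accuracy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewstriage)
```

## The problem

Early warning systems score routine vital-sign observations against banded
thresholds and escalate care when the total crosses a trigger. Pregnancy
shifts normal physiology (blood volume, heart rate, blood pressure), so
obstetric-specific charts (MEOWS) re-draw the bands of the general adult
chart (EWS). This package implements both charts for the postpartum
high-dependency-unit (HDU) setting, classifies each woman by her worst
observation over the stay, and evaluates both charts as screening tests for
severe maternal morbidity (ACOG criteria, consumed here as a supplied
binary label).

## The scoring engine

Each chart is a list of parameter rules; each rule a list of bands mapping
a value region to 1--3 points. The engine is data-driven: the built-in
charts serialize to YAML (`write_scoring_system()`) and read back
bit-exactly, so the encoded thresholds are auditable as plain text.

Three reading conventions, fixed once and applied literally:

* Printed intervals `a–b` are closed `[a, b]`; `<x` / `>x` are strict;
  `≥7` is closed. No rounding is applied before lookup.
* A value matching several overlapping bands (systolic pressure exactly
  150 or 160; heart rate 120, 130, 50 or 60; pain score 7) takes the
  **maximum** points. A warning chart exists to escalate; ties resolve
  upward.
* A value matching no band scores 0 — including values inside genuine
  printed gaps of the general chart (heart rate exactly 40 or 130,
  respiratory rate exactly 30, systolic pressure 70). These gaps are
  honored literally, never silently bridged, but `validate_observation()`
  flags them. A zero-score interval is reported as a gap when it is
  squeezed between two scoring bands, is at most one unit wide, and does
  not contain the parameter's typical resting value — that last condition
  keeps the chart's deliberate normal region (e.g. temperature
  36.6--37.5 °C on the general chart) from being flagged.

Two literal-reading consequences worth knowing: the obstetric chart's
heart-rate band `50–60 → 2` includes the clinically normal 60, and the
general chart's temperature row has no 3-point band (its printed column is
empty). Both are encoded exactly as printed.

Missing parameters score 0 and are counted (`n_missing`); there is no
imputation, matching chart practice where an unmeasured value simply
cannot trigger.

## Triage and aggregation

Observation totals map to ordered categories:

* MEOWS: `red` for totals ≥ 7; `yellow` for totals 5--6 **or** any single
  parameter scoring 3; `green` for totals 1--4; `none` for 0. A total of
  zero sits below the printed green range, and the reference cohort's
  accuracy table is arithmetically incompatible with folding score-0 women
  into green (the green-row specificity of 58% requires the 140 zero-score
  women outside it), so `none` is a distinct stratum.
* EWS: `inform` (notify a physician) for totals ≥ 2; `emergency` (call
  the emergency team) for totals ≥ 4.

A stay is summarized by its **worst** observation under each chart. The
alternative (a fixed assessment time) is not stated anywhere we could
anchor it, and worst-over-stay is the semantics under which a warning
chart operates: any single crossing triggers. The chart's
clinical-deterioration override — a red escalation on clinical grounds
regardless of score — is not computable from vitals; an optional
`red_override` column forces the category for such stays.

## Diagnostic accuracy

For each of six test definitions (red-or-yellow, red, exclusive yellow,
exclusive green, inform, emergency) the 2×2 matrix against the morbidity
label yields sensitivity, specificity, predictive values and likelihood
ratios. The interval methods are a design decision, chosen as the
standard triplet used by common diagnostic-test calculators and verified
to reproduce the reference cohort's printed intervals:

* **Sensitivity/specificity**: exact Clopper–Pearson from beta quantiles.
* **PPV/NPV**: standard logit method with the prevalence-form variance,
  e.g. `var(logit PPV) = (1−se)/(se·n₁) + sp/((1−sp)·n₀)` with
  `n₁ = tp+fn`, `n₀ = fp+tn`.
* **Likelihood ratios**: log method,
  `SE(ln PLR) = √(1/tp − 1/n₁ + 1/fp − 1/n₀)` and the analogous NLR form.

Sample prevalence `(tp+fn)/N` is used throughout; no external prevalence
adjustment. Zero cells are not continuity-corrected: a degenerate interval
is returned with its `degenerate` flag set, because correction would
silently change published-comparable numbers.

Rounding is presentation-only (`format_report()`), applied after all
computation: proportions print as integer percent, half-up; a proportion
cell whose point estimate is below 1% switches to one decimal as a whole;
ratios print to one decimal except values below 0.05, which keep two.

## The reference counts

The source cohort's per-definition 2×2 counts (`reference_counts()`) are
reconstructed by integer enumeration over the denominators 24 (morbid) and
699 (non-morbid): the red and emergency rows are pinned uniquely by the
printed sensitivity and PPV; the yellow, green and inform rows are
constrained to small candidate sets by the printed specificity, PPV and
PLR and fixed by requiring the four exclusive strata to partition the 699
non-morbid women (6 + 259 + 294 + 140). The enumeration is re-run as a
test (`test-reference-counts.R`). One printed cell resists the consistent
solution: the green-row PLR upper bound (we compute 0.749, printing 0.7,
against a printed 0.8, which would require fp = 290 and break the
partition); that row's counts are not uniquely determined and its
intervals are not used as checks.

## The synthetic cohort generator

`generate_cohort()` exists so the full pipeline is testable without
patient records. Its defaults are the study conditions: 723 women, 13
observations each (every 4 h for 48 h), morbidity prevalence 24/723, cause
mixture hypertensive 13/24, hemorrhage 8/24, pulmonary 2/24, anesthesia
1/24, and worst-category frequencies equal to the reconstructed table
(morbid: red 14/24, yellow 8/24, green 2/24; non-morbid: 6/699, 259/699,
294/699, none 140/699).

The generative contract is exact, not approximate: every woman draws a
target worst category from her group's table; baseline observations are
sampled inside the zero-score region of **both** charts (e.g. respiratory
rate 12--14, temperature 36.6--37.2 °C, systolic pressure 101--139); one
observation is overwritten with a cause-consistent deteriorated pattern
built from bands that sum to the target category (hypertensive → blood
pressure, hemorrhage → tachycardia/desaturation/pain, pulmonary →
respiratory rate/SpO2/oxygen, anesthesia → consciousness/pain). Yellow
targets split evenly between the two routes to yellow (total 5--6, or a
single 3-point value with total ≤ 4). Every stay is re-scored and any miss
regenerated, so the configured frequencies are the exact conditional
probabilities and the round-trip property — scoring a generated cohort
recovers the configured operating characteristics up to multinomial noise
— holds by construction.

The general chart's margins are targeted best-effort only: a separate
observation receives low-grade abnormalities that score on the general
chart but not the obstetric one (mild hypothermia 36.1--36.5 °C +
respiratory rate 15--20 for `inform`; plus heart rate 101--109 and
systolic pressure 90--100 for `emergency`), drawn at the reference rates
(inform 15/24 morbid, 238/699 non-morbid; emergency 2/24, 6/699).
Deteriorated obstetric observations can add incidental EWS points (a
hemorrhage heart rate above 130 is 3 EWS points; an altered conscious
level scores on both charts), so realized EWS-positive rates overshoot the
configured margins by several points, most visibly among morbid women. The
joint distribution of the two charts is not identified by the published
margins; accuracy checks for the general chart therefore run on the
reference counts, not on simulated cohorts.

Covariates are drawn per outcome group to match the reported summaries:
split-normal distributions reproducing each median and interquartile range
(age, body-mass indices, gestational age), reported proportions for
parity, twins and delivery mode, and a discrete length-of-stay
distribution with the reported median/IQR/range. Blood loss in the morbid
group is modeled as bimodal — moderate bleeds around the 500 mL median
plus a massive-hemorrhage subgroup beyond the 1630 mL upper quartile —
which respects the reported quartiles exactly; a single right-skewed
component with that IQR would leave the sample median poorly determined
even at large n.

What the generator does **not** emulate: autocorrelated deterioration
trajectories (each stay is baseline plus isolated abnormal observations),
treatment effects on vitals, missing measurements, and any joint
vital-sign correlation beyond the cause patterns. Passing round-trip tests
therefore demonstrates that the scoring, triage and accuracy layers are
correct and mutually consistent — not that the generator reproduces real
bedside dynamics.

## Problem sizes and tolerances in the tests

The suite checks band lookup against a brute-force oracle on a 0.1-step
grid over plausible ranges of all nine parameters; Clopper–Pearson
coverage exhaustively for n ≤ 30 against a binomial-tail oracle; the
round trip over 200 cohorts of 723 women (seeds 1--200), requiring the
mean red-or-yellow sensitivity and specificity to sit within 3 Monte-Carlo
standard errors of 22/24 and 434/699; and covariate medians at n = 10,000
within 5% of the reported group medians. `scripts/acceptance.R` recomputes
the reference table from scratch and repeats the round trip over 50
cohorts.

## Known limitations

* The reference counts for the yellow, green and inform rows rest on the
  partition assumption; the published numbers alone bound but do not pin
  them.
* The generator's vital-sign profile parameters (means/SDs inside each
  band) are free constants chosen for plausibility and sampling
  efficiency; they are not estimates of real postpartum distributions.
* Calibration reflects a single tertiary-center HDU population; nothing
  here validates either chart in other settings.
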