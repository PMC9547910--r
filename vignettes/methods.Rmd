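---
title: "Methods: claims-based chronicity classification and its validation against the GCPS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based chronicity classification and its validation against the GCPS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronicity)
```

## The problem

A payer can compute, for every insured person, a rule-based *chronicity
class* (CC 1/2/3) of back pain from routinely collected claims —
diagnoses, prescriptions, sick-leave episodes — without asking the patient
anything. The Graded Chronic Pain Scale (GCPS) measures the same construct
from the patient's own report. This package implements both instruments
and the machinery to quantify how well the administrative prediction
agrees with the self-reported reference: the criterion-validity question
that decides whether claims data alone can steer care-programme
recruitment.

## GCPS scoring

Seven items: three pain-intensity ratings and three activity-interference
ratings on 0–10, plus disability days in the last six months (0–180).

* characteristic pain intensity = mean of the three pain items × 10
  (0–100, kept as an exact fraction, never rounded);
* disability score = mean of the three interference items × 10;
* disability-days points: 0–6 → 0, 7–14 → 1, 15–30 → 2, 31–180 → 3;
* disability-score points: 0–29 → 0, 30–49 → 1, 50–69 → 2, ≥ 70 → 3;
* disability points = day points + score points (0–6);
* grade: points ≤ 2 and intensity < 50 → I; points ≤ 2 and intensity
  ≥ 50 → II; points 3–4 → III; points 5–6 → IV.

Two scoring constants — the score-point cutpoints and the intensity
threshold 50 — are not unique across GCPS variants; this package fixes
them to the original von Korff instrument, the scoring authority the
validation design itself invokes. All thresholds are inclusive at the
upper category (intensity exactly 50 is grade II), a single half-open
binning convention applied everywhere.

Degenerate inputs: a response of all zeros (no pain, no disability) is
still graded I — the four-grade codomain has no "pain-free" grade — and a
warning is attached. Missing or out-of-range items are hard errors, not
imputation targets: the digital assessment that generates such data makes
completion mandatory, so a missing item indicates a data defect.

## Chronicity classification

Features are counted over a **closed** 365-day window ending at the index
date (the invitation date; records dated exactly on either boundary
count):

* `m_diag_count`: diagnosis records whose 3-character ICD-10 root lies
  lexically in [M40, M54] — any 4th/5th digit matches;
* `f_diag_count`: records matching the psychiatric risk list (F32\*,
  F33\*, F34.1, F34.8, F34.9, F38\*, F41.2, F45.4, F48.0, F43.20, F43.21,
  F43.22, F54\*, F62.80) — starred or stem-only entries match by prefix,
  fully specified codes exactly;
* `opioid_rx_pair_within_window`: two ATC N02A prescriptions at most 183
  days apart ("within six months"), evaluated as a sliding pair window
  inside the lookback year, not anchored to the index date;
* `bp_sickleave_days`: days of overlap between the window and episodes
  attributed to an M40–M54 code, summed cumulatively across episodes.

Classes, with precedence 3 > 2 > 1 and < 2 M diagnoses not classifiable:

* **CC 3**: `bp_sickleave_days` ≥ 42 (six weeks) or an opioid pair;
* **CC 2**: 1–41 sick-leave days, or ≥ 2 F diagnoses;
* **CC 1**: otherwise.

Three readings were genuinely open and are fixed as follows. (1) "Less
than six weeks" of incapacity for CC 2 requires *at least one* attributed
sick-leave day; a literal zero-inclusive reading would let CC 2 absorb
every non-CC 3 case and leave CC 1 empty. (2) Diagnoses are counted as
*records*: the same code on two dates counts twice, two codes on one date
count twice — the rules are phrased over billing records, and
quarter-based claims legitimately repeat codes. A `dedupe_diagnoses`
switch exists for sensitivity analyses. (3) The opioid six-month window
slides; an anchored reading ("≥ 2 in the final six months") is a stricter
variant obtainable by shortening `lookback_days`.

All thresholds (`lookback_days` 365, `opioid_window_days` 183,
`sickleave_chronic_days` 42) are `cc_config()` parameters in days.

## Cohorts

The selection cascade nests three analysis sets: persons with at least one
invoice in the closed 365-day window before *enrolment* (the cost cohort —
deductible tariffs make zero-invoice persons uninformative), of those the
invited persons who enrolled within 90 days of invitation (validation
cohort; inclusive boundary, since those who took *more than* 90 days are
excluded), and of those the sick-leave-insured (subgroup for the
sensitivity analysis, since sick-leave underreporting attenuates the rules
for the rest). Note the two different anchors: invoice availability is
anchored at enrolment, the classifier lookback at invitation.

## Validation metrics

The 4-grade GCPS is collapsed (I+II → 1, III → 2, IV → 3) for the ordinal
3 × 3 comparison — Spearman's rho with average ranks for ties and Cohen's
weighted kappa — and both scales are dichotomised (severe = GCPS III–IV =
CC 3) for the 2 × 2 comparison: sensitivity, specificity, proportion
correct, MCC and kappa. For 2 × 2 tables every kappa weighting coincides
with the unweighted statistic (an identity the tests assert exactly).

Numerical choices:

* the 3 × 3 kappa defaults to **linear** weights — the weighting is not
  identifiable from the published 2 × 2 material, and linear weights are
  the conservative ordinal default (quadratic weights are available);
* the kappa standard error is the large-sample Fleiss–Cohen–Everitt
  formula for weighted kappa; the rho interval uses the Fisher
  z-transform with the Fieller–Hartley–Pearson variance `1.06/(n − 3)`.
  Both intervals are asymptotic approximations, adequate at the cohort
  sizes involved (n ≈ 10³) but not exact small-sample intervals;
* degenerate margins (an empty predicted or observed class) make MCC
  undefined; the package returns 0 with a warning instead of failing, so
  stochastic simulations never crash on an extreme draw;
* display rounding is one-decimal percent for proportions and three
  decimals for correlations; internal values stay unrounded.

The verbal bands (rho: weak/modest/moderate/strong/very strong; kappa:
poor/fair/moderate/substantial/almost perfect; MCC: very weak/fair/
moderately strong/very strong) are implemented with each band inclusive at
the lower edge of its published interval.

## Cost analysis

Per person and category (total health, BP inpatient, BP outpatient, and
derived BP total), invoice amounts in the pre-enrolment year are summed
after CPI conversion to base-year (2020) euros. The shipped CPI table is
an editable placeholder series for Germany 2013–2021. High-cost cases lie
strictly above the Tukey fence `Q3 + 1.5·IQR`; quartiles use linear
interpolation between order statistics (quantile type 7) — the convention
is not identifiable from published material, so it is fixed and
documented, and published skewness values are treated as qualitative
checks only. Only the upper fence is used (costs are bounded below by
zero). Fences are computed once per category on the whole cohort, not per
grade group: per-group outlier percentages are only comparable under a
common fence. Low-cost cases are presence-based — no invoice of the
category in the window, regardless of amounts. The truncated mean removes
both flag types; skewness is the adjusted Fisher–Pearson standardised
third moment (`e1071::skewness(type = 2)`).

## The synthetic generator

Real claims and questionnaire data of this kind are access-restricted, so
`generate_population()` fabricates a cohort whose *joint* structure mirrors
the validation study's published conditions:

* enrolment path invited with probability 2722/3506, invitation-to-
  enrolment delay exponential with mean 42.4 days (≈ 12 % beyond the
  90-day window), sick-leave insurance 46.1 %, no-invoice persons
  123/3629;
* for invited persons an intended CC is drawn and the intended GCPS grade
  follows the published CC-conditional grade distributions; self-selected
  persons get the published self-selected grade distribution, and their
  CC is *computed* from their generated claims, never drawn (15 % of them
  receive claims below the two-diagnosis minimum and are not
  classifiable);
* claims are then constructed to *guarantee* the intended class: CC 3
  draws either a ≥ 42-day attributed episode or an opioid pair ≤ 183 days
  apart; CC 2 either 1–41 attributed days or ≥ 2 listed F diagnoses;
  everyone else stays below those triggers (at most one opioid
  prescription, so no accidental pair can form). All records fall inside
  the lookback window;
* GCPS items are drawn uniformly from the preimage of the intended grade
  (rejection sampling over the discrete item grid), so rescoring
  reproduces the grade exactly;
* annual cost totals are lognormal per grade and category with locations
  rising in grade, anchored to the published per-grade means (the BP
  inpatient anchors are smoothed to (120, 200, 464, 1021) € to keep the
  intended strict ordering robust to sampling noise, since the published
  grade I/II pair is non-monotone and nearly tied while the category is
  ~95 % zeros and heavy-tailed), zero-invoice probabilities per grade from the published
  low-cost percentages, totals drawn in base-year euros and deflated to
  nominal invoice-year amounts so that CPI adjustment in the pipeline
  recovers them.

Two published quantities over-determine the design: the CC-conditional
grade rows, the overall grade marginal and the CC margin of the validation
table cannot all hold simultaneously (they were computed on different
denominators and rounded to printed precision). The package keeps the
printed conditional rows exactly and calibrates the one unpublished
quantity — the CC mix among invited persons — to (0.665, 0.110, 0.225),
which reproduces the overall grade marginal to within 0.7 percentage
points and places the implied 3 × 3 rho and weighted kappa in the
published "moderate" and "fair" bands. This calibration was fixed once, at
design time, from the published marginals alone;
`generator_expected_metrics()` exposes the closed-form operating
characteristics implied by any configuration so simulations can be checked
for parameter recovery rather than against hard-coded numbers.

Randomness: one seeded RNG drawn in a fixed stage order (persons → claims
→ questionnaire → invoices). A fixed seed therefore yields a
byte-identical CSV bundle; inserting a new record type would perturb
downstream draws, which is accepted in exchange for not hand-rolling a
substream API. The caller's RNG state is saved and restored.

What the generator does **not** emulate: temporal disease progression,
realistic billing tariffs and invoice counts, correlation between the
GCPS items beyond what the grade preimage enforces, comorbidity structure,
and any dependence of self-selected persons' grades on their latent claims
profile. Passing round-trip tests therefore demonstrate that the pipeline
computes its statistics correctly under the published marginal structure —
not that the chronicity rules would achieve these operating
characteristics on real insurance data.

## Problem sizes and test design

The unit suite exercises hand-sized fixtures against independent oracles
(brute-force day-by-day window overlap, all-pairs prescription gaps,
explicit Po/Pe enumeration for weighted kappa, rank-then-Pearson for tied
Spearman, moment formulas for skewness) plus property checks under fixed
seeds: grade monotonicity over 1.2 × 10⁵ sampled item-grid points,
classifier/scorer round trips at 10⁴ persons, parameter recovery and band
membership at 10⁵ persons, and 300 lognormal replicates for the
skew-reduction property. These sizes keep the full suite under a minute
on a single core while leaving Monte-Carlo error an order of magnitude
below every asserted tolerance.

## Known limitations

* The asymptotic kappa/rho intervals are approximations; no bootstrap or
  exact small-sample intervals are provided.
* ICD-10 matching is purely syntactic on code strings; no terminology
  service or German ICD-10-GM catalogue validation is performed.
* The cost stage models billed amounts only — no reimbursement-vs-billed
  distinction, deductibles, indirect costs or discounting.
* The supplementary 3 × 3 cell counts of the original study were not
  published; the generator's conditional completions are documented
  approximations, not ground truth.
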