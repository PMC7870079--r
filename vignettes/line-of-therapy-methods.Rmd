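---
title: "Deriving treatment lines for advanced colorectal cancer from claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving treatment lines for advanced colorectal cancer from claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crclot)
library(dplyr)
```

## The problem

Hospital claims record drug dispensations, diagnoses, procedures and
assessments — but not the clinical construct oncologists reason in: *lines
of therapy*. For advanced colorectal cancer (CRC), questions such as "how
many patients go on to second-line treatment?", "which regimens follow
which?", or "what predicts early discontinuation of second-line
antiangiogenic therapy?" all require reconstructing lines from dated
prescription events, under explicit, testable rules. `crclot` implements
such a rule system end to end: cohort selection, line derivation, sequence
and prescription analytics, and the Kaplan–Meier / logistic / Cox stages,
together with a synthetic claims generator whose latent line structure is
known, so the whole pipeline can be validated against ground truth.

## Data model

A *claims bundle* is six tables (patients, hospitals, diagnoses,
prescriptions, procedures, assessments) linked by opaque identifiers; see
`?claims_bundle_format`. Two conventions matter throughout:

* **All interval arithmetic is in integer days** on ISO-8601 calendar
  dates. Month-based rules use fixed day counts: 3 months = 91 days,
  6 months = 183 days, 1 year = 365 days. Durations reported on the month
  scale divide by 30.4375.
* **Each patient carries a `data_end`** — the final date of data provided
  by the hospital. The 60-day rules compare against this horizon, not
  against the last observed claim, because "no more claims" is only
  informative when the hospital's data extends beyond them.

Drugs resolve through a small vocabulary (`drug_vocabulary()`) classifying
the guideline-listed antitumor agents (fluoropyrimidines, oxaliplatin,
irinotecan, FTD/TPI, the three antiangiogenic antibodies, the two anti-EGFR
antibodies, and other targeted agents), concomitant classes used as
covariates, and leucovorin, which is a modulator: it appears inside regimen
names (FOLFOX, FOLFIRI) but never starts or ends a line by itself.
`is_biologic` is true exactly for the five monoclonal antibodies; only
these participate in the biologic-addition exception below. Each drug has a
`default_cycle_days` used for expected-final-dose dates when a prescription
carries no `days_supplied`: 14 for drugs given on biweekly schedules, 21
for capecitabine/S-1/FTD–TPI oral cycles, 28 as the generic oral fallback.

## The line-derivation algorithm

For a given patient the first line is anchored at a population-specific
date: the first prescription of bevacizumab, cetuximab or panitumumab
(first-line population), or the first adjuvant drug after resection
(early-recurrence population, whose first line is labelled *adjuvant* and
whose next line is the *second* line — there is no line 1).

1. **Regimen assembly (28-day window).** The line's regimen is the set of
   all antitumor drugs (plus leucovorin) prescribed in
   `[anchor, anchor + 27]`. Regimen names come from an exact-set match of
   the non-biologic drugs against a backbone dictionary (FOLFOX, CAPOX,
   FOLFIRI, FOLFOXIRI, SOX, IRIS, monotherapies), with biologics appended
   as an ordered suffix; unmatched sets are labelled OTHER with the raw set
   retained.
2. **Line end — whichever fires first.**
   *Gap rule*: the next antitumor prescription arrives 180 days or more
   after the line's running expected-final-dose date (the running maximum
   of `date + days_supplied-or-cycle` over the line's antitumor
   prescriptions). The line ends at that expected-final-dose date. The gap
   clock runs from covered exposure, not from the last prescription date,
   because claims exposure persists to the covered end; this is a
   documented convention, the rules' source does not fix it.
   *New-drug rule*: a prescription contains an antitumor drug outside the
   current regimen. The line ends at that prescription's date, which also
   anchors the next line (half-open intervals `[start, end)`, so lines
   never overlap and durations are `end − start` days).
3. **Biologic-addition exception (lines ≥ 2 only).** A biologic prescribed
   into a regimen that is still chemotherapy-only is recorded as a regimen
   *addition*, not a line end. The exception is narrow: it never applies to
   first-line or adjuvant therapy; a prescription introducing a biologic
   *and* a new non-biologic drug triggers a new line; so does a second
   biologic when the regimen already contains one.
4. **Censoring and completion (60-day rules).** The last line ends at
   `min(expected final dose date, data_end)`. A line is *evaluable for
   transition* when a next line exists or strictly more than 60 days of
   data remain after its end — otherwise non-transition is not observable
   and the patient is excluded from transition denominators. Treatment is
   *completed* when 60 days or more separate the expected final dose date
   from `data_end`; otherwise the duration record is censored at the
   expected final dose date. The strict/non-strict asymmetry ("more than
   60" for evaluability, "60 or greater" for completion) is deliberate and
   boundary-tested.

A same-drug restart after a ≥180-day gap starts a new line: the gap rule is
stated unconditionally. Re-challenge lines can be recognised downstream by
comparing regimen labels across adjacent lines.

## Cohort selection

Two disjoint populations are selected by rule, each with a criterion-level
attrition log:

* **First-line population** — presumed advanced/metastatic disease: a
  confirmed C18–C20 diagnosis inside the diagnosis window; a first
  qualifying antibody prescription after it (the anchor); age ≥ 20 at the
  anchor (claims carry birth year only, so age uses an assumed July-1
  birthday); no qualifying antibody in the 365 days before the anchor;
  not eligible for the early-recurrence population; no non-guideline
  antitumor drug at any time; anchor on or after the enrollment start.
* **Early-recurrence population** — presumed relapse after curative-intent
  treatment: resection after diagnosis; adjuvant therapy (capecitabine,
  5-FU, S-1, UFT, oxaliplatin) within 91 days of surgery; no biologic
  before resection and none added within 91 days of chemotherapy start; a
  switch to second-line therapy within 183 days of the last adjuvant
  dose's *expected final dose date* (a prescription database proxies "last
  dose" best by covered end, consistent with the censoring rule).

All windows are closed on both ends. The index date is the first
second-line prescription date; since that requires derived lines, cohort
rows carry `index_date = NA` until `assign_index_dates()`. RAS mutation
status is absent from claims, so it is *presumed*: wild-type iff any
anti-EGFR antibody prescription exists anywhere in the analysis window.
The FOLFIRI-plus-antiangiogenic subpopulation holds members whose second
line's initial 28-day regimen is exactly the FOLFIRI backbone plus at
least one antiangiogenic drug; the subpopulation drug is the earliest
antiangiogenic in that window, ties broken bevacizumab < ramucirumab <
aflibercept beta, with multi-antiangiogenic windows retained and flagged.

## Statistical stages

* **Transition rates**: per population × presumed-RAS stratum and
  consecutive line pair, `100 × transitioned / evaluable`, rounded half-up
  to one decimal (the reporting convention for all percentages); zero
  evaluable patients yield an absent rate, never 0. The adjuvant-to-second
  pair is excluded for the early-recurrence population (100% by
  definition).
* **Second-line antiangiogenic report**: per-patient antiangiogenic
  prescription counts, single use (exactly one prescription), dose
  reductions (a same-drug prescription strictly below its immediate
  predecessor, both doses present — claims carry no planned dose to
  compare against), and ≥21-day gaps between consecutive prescription
  dates (a ≥7-day slip against the biweekly schedule; gaps use
  prescription dates, not covered ends, by definition). Percentages use
  the evaluable denominator.
* **Kaplan–Meier**: product-limit estimate of second-line antiangiogenic
  treatment duration (second-line start to last antiangiogenic expected
  final dose). The median is the first time the estimate falls to 0.5 or
  below; confidence intervals use the log-log transform; the restricted
  mean is flagged as underestimated when the largest observation is
  censored. The event indicator is "treatment completed": a third line
  exists, or ≥ 60 days of data follow the last antiangiogenic expected
  final dose — an observed next line proves the second-line treatment
  ended even when the data horizon is close.
* **Logistic stage**: single vs multiple antiangiogenic prescriptions on
  11 baseline covariates (hospital designation, age ≥ 70, sex, left-sided
  disease, presumed RAS-wild-type, BMI ≤ 18.5 kg/m², Barthel ADL below
  100, oral fluoropyrimidine or irinotecan in the previous line, previous
  line ≥ 180 days, early recurrence). Maximum likelihood, Wald 95%
  intervals; separation is flagged, never silently returned.
* **Cox stage**: overall treatment duration from second-line start to the
  last antitumor expected final dose across all subsequent lines, on the
  logistic covariates plus five concomitant-exposure flags measured inside
  the second line (qualitative/quantitative proteinuria testing,
  antihypertensives, anticholinergics, anticoagulants). Efron tie
  handling, because day-granularity claims are heavily tied; Wald
  intervals. The source analyses name their software but not their tie or
  CI conventions, so these are package choices, documented rather than
  inferred. No multiple-testing adjustment, matching the exploratory
  framing. Both models are complete-case: rows with missing BMI/ADL are
  excluded and counted, never imputed.

Baseline covariates derive only from events in `[index − 365, index]`;
sidedness comes from confirmed diagnosis codes (right: C18.0–C18.4; left:
C18.5–C18.7, C19, C20; both flags may hold simultaneously, neither for
C18.8/C18.9-only patients); BMI and Barthel use the latest assessment in
the window, with "ADL not independent" meaning a Barthel total below 100.

## The synthetic claims generator

`simulate_bundle()` writes *prescriptions, not lines*: each patient gets a
latent timeline (population pathway, regimens drawn from weighted menus,
line durations, transition decisions), and only its claims encoding is
emitted. Recovering the latent structure is exactly the derivation
algorithm's job, which makes "derived lines equal truth lines on noise-free
data" a meaningful oracle test rather than bookkeeping.

The default configuration is the stated world the pipeline targets:
enrollment May 2016 – July 2019; ~9% early-recurrence patients; ~30%
anti-EGFR-containing histories (presumed wild-type); transition
probabilities 0.60/0.60/0.55/0.50 toward lines 2–5, near the reported
transition-rate scale; first-line menus dominated by FOLFOX/CAPOX plus
bevacizumab (presumed mutant) or FOLFOX plus panitumumab (presumed
wild-type) and second-line menus dominated by FOLFIRI-based regimens;
biweekly antiangiogenic dosing with a 20% chance per interval of a 7–28-day
delay (hence ≥21-day gaps); ~12% of patients missing BMI and ADL
assessments; 12% antiangiogenic dose-reduction probability; a 15% chance
that a single-biologic regimen in lines ≥ 2 starts chemotherapy-only with
the biologic arriving after the 28-day window (exercising the addition
exception). Overall treatment duration from second-line start follows an
exponential proportional-hazards mechanism (baseline hazard log(2)/240 per
day, i.e. an 8-month median at covariate zero) with default log-hazard
ratios shaped like the associations the Cox stage is designed to estimate;
the single-dose outcome follows a logistic mechanism (baseline ~10%, odds
raised by old age and dependent ADL, lowered by presumed wild-type status
and early recurrence). The per-patient data horizon is the last claim plus
a uniform 0–400-day lag, which produces roughly one censored duration in
five. Where the emulated study reports no value (cycle jitter, menu
weights, the lag law), values were chosen once as field-plausible and are
not revisited.

Internal consistency rules keep truth and derivation aligned: a next line
is generated with a new-drug boundary only when its day-0 drug set would
actually trigger one under the derivation rules (including the
biologic-absorption case for previous lines ≥ 2); otherwise the transition
is generated as a ≥180-day gap. Truth RAS labels and the single-use outcome
are recorded from the *emitted* claims, not the drawn intent, so the
recovery invariants test the rules, not the generator's bookkeeping.

What the generator does **not** emulate: real Japanese billing code
systems, hospital case-mix and visit frequency, dose tapering beyond the
single reduction step, deaths (discontinuation is absorbed into the data
horizon), within-patient BMI drift, or correlated covariates. A green test
therefore establishes that the rules are implemented as stated and that
the statistical stages recover known mechanisms — not that the pipeline
reproduces any real-world estimate, which would require the proprietary
source database.

Parameter-recovery checks (logistic odds ratio 2.0; Cox hazard ratio 1.5;
null calibration at the 5% level) run on `simulate_outcomes()`, the same
covariate/outcome mechanism the bundle generator uses, drawn directly at
n = 2,000 across seeded replicates; the full claims path is exercised
separately by the oracle-equivalence and end-to-end tests. Running twenty
full 2,000-patient claims simulations would spend minutes to test exactly
the same estimation code path.

## Numerical and degenerate-input choices

* Percentages round half-up to one decimal (with a 1e-9 guard against
  binary representation at .5 boundaries); `round()`'s round-to-even is
  never used for reported rates.
* A zero denominator yields `NA`, and an empty subpopulation yields an
  empty report, not zeros.
* An empty prescription list derives zero lines; a prescriptions table
  whose anchor date carries no antitumor drug is an error.
* Logistic separation (including a one-level outcome) aborts or flags
  non-convergence; a Cox fit without events aborts.
* `capecitabine` uses a 21-day default cycle (14 days on, 7 off — the
  CAPOX convention); UFT keeps the generic 28-day oral fallback.
* The Kaplan–Meier median convention (first time at or below 0.5) differs
  from averaging conventions only when the curve hits exactly 0.5.

## Known limitations

* Presumed RAS status misclassifies wild-type patients who never received
  an anti-EGFR antibody; it is a proxy, stated as such.
* Line derivation sees only dispensations: dose interruptions without a
  prescription gap, and in-hospital administrations missing from the
  extract, are invisible.
* The 180-day gap and 60-day completion rules are heuristics; patients
  with very long cycle drugs interact with them through
  `default_cycle_days`, so vocabulary edits change line boundaries.
* The generator's covariates are drawn independently; real claims
  covariates are correlated, so model-stage performance on real data may
  differ from the recovery results.
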