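---
title: "Trigger-tool screening for adverse drug events: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trigger-tool screening for adverse drug events: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adetrigger)
```

## The surveillance problem

Spontaneous reporting detects only a small fraction of adverse drug events
(ADEs) in hospital. The Global Trigger Tool (GTT) approach replaces
exhaustive chart review with a two-stage design: a cheap, fully mechanical
*screen* flags admissions showing any of a fixed set of "triggers" —
laboratory threshold crossings, antidote or rescue-medication use,
symptomatic events, deterioration outcomes, or supratherapeutic drug
concentrations — and a review panel then *adjudicates* only what the screen
surfaces, attributing causality and grading harm. `adetrigger` implements
the full quantitative machinery of this workflow for a specific high-risk
population: inpatients aged 65 or older with two or more chronic diseases
and polypharmacy (five or more concurrent medications).

The package deliberately separates the two stages. Screening is purely
observational — a trigger fires on evidence in the record, with no causal
reasoning and no drug linkage. All attribution lives in the adjudication
table, which records, per candidate event, the suspect drug and its class,
the organ system involved, the ten Naranjo answers and the NCC MERP
severity grade. This mirrors how trigger-tool studies are actually run and
keeps the screen auditable.

## The trigger registry

The packaged default registry holds 38 rules tuned to elderly multimorbid
inpatients. Every rule is declarative data (YAML), not code: a category, a
combinator and a list of atoms. Three design choices matter:

* **Comparators are strict.** A potassium of exactly 3.5 mmol/L does not
  fire the hypokalemia rule (`K < 3.5`). Thresholds are used exactly as
  written in the registry, and units are never converted — a lab row whose
  unit differs from the analyte's canonical unit is a hard error at
  ingestion, because silent unit conversion is the classic failure mode of
  automated trigger tools.
* **Multi-analyte rules.** The renal rule (CK, BUN, sex-specific
  creatinine) and the hepatic rule (ALT, AST, ALP, TBIL) combine their
  atoms with `any_of`: each analyte is an alternative signal of the same
  clinical concern, so any abnormal value fires the rule once. The two
  thyroid rules instead use `all_of`: a suppressed TSH only means
  drug-induced hyperthyroidism together with an elevated thyroid hormone,
  so the full biochemical pattern is required. Whether the original
  deployments applied the multi-analyte rules disjunctively is not
  documented anywhere we know of; `any_of` is the defensible default and a
  user config can flip it without code changes.
* **One hit per admission.** A trigger counts once per (patient, trigger)
  pair no matter how many results qualify; the earliest qualifying record
  supplies the evidence string. This makes per-trigger counts patient-level
  quantities, which is the convention under which positive predictive
  values are reported.

Sex-restricted atoms (creatinine: > 111 umol/L for men, > 81 umol/L for
women) are evaluated against the patient's recorded sex. Laboratory rows
for analytes outside the canonical registry are ignored with a warning —
a screen must never abort because an EHR extract contains extra columns.

## Causality and severity

Naranjo scoring uses the canonical published item weights (Q1 +1; Q2 +2/-1;
Q3 +1; Q4 +2/-1; Q5 -1/+2; Q6 -1/+1; Q7-Q10 +1 for yes; "do not know"
scores 0 everywhere), with categories definite (>= 9), probable (5-8),
possible (1-4) and doubtful (<= 0). Doubtful candidates are treated as
non-drug-related: they are excluded from every ADE analysis but retained in
an audit list, so the exclusion is visible rather than silent. In generated
adjudications item 6 (placebo rechallenge) is uniformly "unknown", since
rechallenge is ethically unavailable in routine inpatient care.

Severity uses the NCC MERP ladder restricted to grades E-I (temporary harm
requiring intervention, through death). Grades A-D involve no substantive
harm and are rejected at validation: a trigger tool measures harm, not
near-misses.

## The quantitative outputs

Let the screen and the adjudication cross-classify the `N` admissions into
`tp` (trigger-positive with at least one ADE), `fp`, `fn`, `tn`. The
screening evaluation reports

* sensitivity `tp/(tp+fn)` and specificity `tn/(tn+fp)`,
* the *compliance rate* — the trigger-tool literature's name for overall
  agreement `(tp+tn)/N`,
* Cohen's unweighted kappa `(p_o - p_e)/(1 - p_e)` with
  `p_o = (tp+tn)/N` and
  `p_e = [(tp+fp)(tp+fn) + (fn+tn)(fp+tn)]/N^2`, and
* the patient-level positive predictive value `tp/(tp+fp)`.

All of these are ratios of small integers, so they are evaluated in exact
integer arithmetic and only rounded at the reporting boundary: half-up to
two decimals on the percentage scale. Half-up matters — `93/480` is
exactly 19.375%, which must print as 19.38, and IEEE binary-float rounding
would get it wrong. A metric whose denominator is zero is reported as
undefined with a flag, never as NaN.

Rates follow the GTT conventions: ADEs per 1,000 patient-days
(`1000 * ADEs / sum of lengths of stay`), ADEs per 100 admissions, and the
patient-level incidence. Per-trigger performance divides each trigger's
adjudicated ADE cases (screening hits of that trigger linked to at least
one non-doubtful ADE) by its positive firings; a trigger that never fired
reports 0.00 with a zero-denominator flag rather than an undefined value,
matching how such rows are conventionally printed.

## Risk-factor statistics

The package implements its own Pearson chi-square (uncorrected — no Yates
continuity correction, which is what reproduces published trigger-tool
chi-squares), Mann-Whitney U (midranks, tie-corrected normal variance, no
continuity correction, U oriented to the first sample), binary logistic
regression and rank-based ROC/AUC, each cross-checked in the test suite
against an independent reference (`chisq.test`, `wilcox.test`, `glm`,
`pROC`) and against brute-force enumeration oracles.

The logistic fitter is plain iteratively reweighted least squares:
convergence when the largest absolute score component falls below `1e-8`
or the relative log-likelihood change below `1e-10`, capped at 100
iterations. Wald 95% intervals (`exp(beta +/- 1.96 se)`) are reported for
odds ratios, matching standard statistical-package output. Rank-deficient
designs are rejected up front; complete or quasi-complete separation is
detected from diverging coefficients with boundary fitted probabilities and
reported as an error naming the offending predictor, because a separated
logistic fit has no finite maximum-likelihood estimate to report.

AUC is computed as the Mann-Whitney concordance probability (ties counted
one half) with a Hanley-McNeil confidence interval. For risk modelling the
package codes age as the ordinal stratum 65-75 / 76-85 / >= 86 (1, 2, 3),
length of stay as 2-13 vs 14-24 days (a stay of exactly 13 days belongs to
the lower stratum), medication count as 5-15 / 16-26 / >= 27, and trigger
positivity as a binary indicator; the original covariate codings behind
published odds ratios for this design are not recoverable without
patient-level data, so those odds ratios are context, not targets.

## The calibration cohort

No real cohort can ship with the package, so `build_calibration_fixture()`
*constructs* one — deterministically, with no randomness — such that
running the full pipeline reproduces every reference count exactly: 480
admissions (263 male, 217 female), 4,062 patient-days, 204 trigger hits
with a fixed per-trigger breakdown, 123 trigger-positive admissions, the
(51, 72, 14, 343) contingency table, 93 ADEs in 65 patients (46 with
exactly one), causality categories 2/5/86 plus two excluded doubtful
candidates, severity 90 E / 3 F, and fixed drug-class and organ-system
counts.

Three reference inconsistencies had to be resolved to make the manifest
internally consistent, and the package resolves them the same way every
time:

* The reported mean stay of 8.38 days over 480 admissions implies 4,022
  patient-days, but 4,062 is the denominator that enters the published
  per-1,000-patient-days rate; the fixture honours 4,062 (its mean stay is
  8.46 days).
* The drug-class table's "other" row is reported as 14 cases but as
  13.98% = 13/93; the fixture uses 13 so the classes partition the 93
  ADEs.
* The overall agreement of the (51, 72, 14, 343) table is 394/480 =
  82.08%, although it is conventionally quoted as 82.00%; the package
  reports the arithmetic result.

The hardest packing constraint is that per-trigger ADE cases sum to 93
while 14 ADE patients are trigger-negative: their ADEs can link to no
trigger. The fixture therefore gives 14 ADEs of trigger-positive patients
two linked triggers each (trigger links are distinct within a patient, so
hit-level and link-level counting agree), and distributes both the 93
ADE-linked hits and the 111 remaining hits with a greedy
largest-remaining-capacity packing. Generation validates every manifest sum
and fails loudly rather than producing a silently wrong fixture. Laboratory
evidence is placed one least-significant unit past each strict threshold
(potassium 3.4 against the 3.5 rule, APTT 39.1 against 39, and so on), so
the fixture also exercises boundary semantics.

What the fixture does *not* emulate: longitudinal laboratory trajectories,
dose-response structure, correlated trigger co-occurrence beyond what the
packing forces, reviewer disagreement, or any real pharmacology. Passing
the calibration suite shows the pipeline computes the right numbers from
the right counts; it says nothing about detection performance on real
records.

## The stochastic simulator

`simulate_cohort()` is the fixture's stochastic counterpart, for
statistical validation rather than calibration. Triggers fire independently
per patient with configurable probabilities (defaults: the reference counts
over 480), and ADE occurrence is drawn from a logistic model in the age
stratum and trigger positivity, so that `fit_logistic()` can be tested for
parameter recovery against a known truth. The default coefficients
(intercept -5.53, +2.70 per age-stratum step, +3.73 for trigger
positivity) were fixed once by least squares against the reference
stratum-specific ADE rates (5.61%, 19.05%, 66.67%) and trigger-margin
rates (41.46% positive, 3.92% negative) under independent firing. All
five margins cannot hold simultaneously — in the real data age and trigger
positivity are correlated, in the simulator they are independent — so the
compromise favours the stratum profile; the implied oldest-stratum rate is
about 64% and the overall ADE rate about 15%.

Length-of-stay and medication-count draws use lognormal weights on the
integer supports 2-24 and 5-46, with location parameters solved so the
truncated means match 8.38 days and 16.05 drugs. Multimorbidity is
enforced: a simulated patient drawn with fewer than two chronic conditions
receives the two most prevalent ones.

The systematic time-based sampler reproduces the study-design stage:
records are bucketed into half-months by admission date (days 1-15 versus
the rest), each record receives an independent uniform draw, and the
`k` lowest draws per bucket are kept — 20 per half-month yields 40 per
month and 480 per year. Buckets shorter than `k` contribute everything
they have, with a warning.

## Numerical and testing choices

Problem sizes were chosen to keep the default test run fast while still
informative: oracle-equivalence properties run on cohorts of 3-25 patients
against a brute-force nested-loop evaluator; kappa is checked against an
explicit margin oracle on 1,000 random tables; law-of-large-numbers and
parameter-recovery checks use 50,000-patient simulations, with recovery
bias measured across six replicate seeds and judged against 0.05 plus twice
the Monte-Carlo standard error of the replicate mean (the rare-event
intercept alone has a single-draw sampling sd near 0.1, so a bare
single-draw bound would measure luck, not bias).

Known limitations: the data model is one admission per record, so
"readmission within 30 days" must arrive as an explicit event code rather
than be inferred across admissions; adjudications are taken at face value
(no inter-reviewer model); preventability is not assessed; and the trigger
engine has no temporal dose-to-event windows — a trigger fires on any
in-stay evidence regardless of medication timing.
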