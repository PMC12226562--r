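# adetrigger

Trigger-tool screening and evaluation of adverse drug events (ADEs) in
elderly multimorbid inpatients.

## What this package is for

Hospitals under-detect medication harm: spontaneous reporting surfaces only
a fraction of adverse drug events. The Global Trigger Tool (GTT) method
addresses this with a two-stage retrospective design. First, a mechanical
**screen** flags admissions that show any of a fixed registry of
*triggers* — abnormal laboratory values (potassium below 3.5 mmol/L, INR
above 1.2, ...), use of antidotes or rescue medications (vitamin K,
flumazenil, naloxone, ...), symptomatic events (edema, rash, falls),
deterioration outcomes (ICU transfer, 30-day readmission) and
supratherapeutic drug concentrations. Second, a review panel
**adjudicates** the flagged records: causality with the 10-item Naranjo
scale (definite >= 9, probable 5-8, possible 1-4, doubtful <= 0, with
doubtful events excluded as non-drug-related) and severity on the NCC MERP
E-I ladder.

`adetrigger` implements this workflow end-to-end for pharmacovigilance and
quality-improvement teams working with structured inpatient data:

* a validated cohort model (demographics, chronic conditions, medication
  orders, laboratory results with canonical units, clinical events) with
  inclusion-criteria enforcement (age >= 65, >= 2 chronic conditions,
  polypharmacy, stay >= 2 days);
* a declarative 38-rule trigger registry (YAML; user-revisable) and a
  screening engine with strict comparators, sex-specific thresholds and
  compound `any_of`/`all_of` predicates;
* Naranjo scoring and category mapping, NCC MERP grade validation, and
  assembly of adjudicated ADE records linked to screening hits;
* the GTT quantitative outputs: sensitivity `tp/(tp+fn)`, specificity
  `tn/(tn+fp)`, compliance rate `(tp+tn)/N`, Cohen's kappa
  `(p_o - p_e)/(1 - p_e)`, patient-level PPV `tp/(tp+fp)`, ADEs per 1,000
  patient-days and per 100 admissions, incidence, per-trigger PPV, and
  severity / drug-class / organ-system distributions — all in exact
  integer arithmetic with half-up rounding at the reporting boundary;
* risk-factor statistics implemented from first principles and
  cross-checked against independent references: uncorrected Pearson
  chi-square, Mann-Whitney U with midrank ties, binary logistic regression
  by IRLS with Wald odds-ratio intervals, and concordance-based ROC/AUC
  with Hanley-McNeil confidence intervals;
* a deterministic 480-admission calibration cohort that reproduces every
  reference count exactly, a stochastic cohort simulator with a known
  logistic ADE-risk model for parameter-recovery studies, and systematic
  time-based (half-month) random sampling.

## Worked example

```r
library(adetrigger)

fix    <- build_calibration_fixture()            # cohort + adjudication table
screen <- screen_cohort(fix$cohort)              # default 38-trigger registry
screen
#> <screen_result> 204 hits | 123/480 trigger-positive patients (25.62%)
#>   [13] K < 3.5 mmol/L                                           43
#>   [17] PLT < 125 x 10^9/L                                       21
#>   [32] Edema                                                    20
#>   [15] Na < 137 mmol/L                                          17
#>   [18] TC > 5.2 mmol/L                                          11
#>   ... and 22 more positive triggers

adj <- build_ade_records(fix$cohort, screen, fix$adjudication)
adj
#> <adjudicated_cohort> 93 ADEs in 65 patients (2 doubtful candidates excluded)
#>   causality: definite 2, possible 86, probable 5
#>   severity:  E 90, F 3

evaluate_screening(two_by_two(screen, adj))
#> Screening evaluation (trigger positivity vs adjudicated ADE status)
#>   Sensitivity          78.46%
#>   Specificity          82.65%
#>   Compliance rate      82.08%
#>   Cohen's kappa        44.40%
#>   PPV (patient-level)  41.46%

s <- summarize_cohort(fix$cohort)
compute_rates(nrow(adj$ades), sum(adj$per_patient$n_ades > 0),
              s$n_patients, s$patient_days)
#> GTT rates
#>   ADEs / 1,000 patient-days: 22.90  (93/4062)
#>   ADEs / 100 admissions:     19.38  (93/480)
#>   ADE incidence:             13.54% (65/480)

chi <- pearson_chi2(two_by_two(screen, adj))
sprintf("chi-square = %.3f (df = %d, p = %.3g)", chi$statistic, chi$df, chi$p_value)
#> [1] "chi-square = 110.125 (df = 1, p = 9.2e-26)"
```

Reading the numbers: of 480 admissions, 123 screened trigger-positive and
65 were adjudicated as having at least one ADE (93 ADE events in total).
The screen catches 78% of ADE patients (sensitivity) while clearing 83% of
ADE-free patients (specificity); agreement beyond chance is moderate
(kappa 44%), and 41% of trigger-positive admissions turn out to harbour an
ADE (patient-level PPV). The harm burden is 22.9 ADEs per 1,000
patient-days. The chi-square confirms the strong association between
trigger positivity and ADE occurrence.

`write_gtt_report()` emits all of the above plus the per-trigger
performance table and the three distribution tables as TSV files and a
plain-text report. A thin command-line wrapper is installed at
`inst/cli/gtt.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "gtt.R", package = "adetrigger"))')" \
  fixture --out cohort_dir
```

with subcommands `fixture`, `simulate`, `screen` and `report`.

## Further reading

The methods vignette (`vignettes/trigger-tool-methods.Rmd`) documents the
model and its assumptions in detail: the trigger predicate semantics,
Naranjo weights and cutoffs, the exact-arithmetic rounding rules, how the
calibration cohort is packed so that every reference count is reproduced
simultaneously, the simulator's risk model and its calibration, and known
limitations.
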