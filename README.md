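# asthmaCMA

Asthma controller adherence, reliever use and outcomes from primary-care
prescription data.

In routine general-practice databases, only issued prescriptions, coded
diagnoses and occasional questionnaires are observed — yet they are enough
to quantify how well patients implement their inhaled-corticosteroid (ICS)
controller regimen, how often they reach for their short-acting
beta-agonist (SABA) reliever, and how both relate to exacerbations and
self-reported asthma control. `asthmaCMA` implements that full analysis as
a tested R pipeline, for pharmacoepidemiologists and health-services
researchers working with such extracts, together with a calibrated
synthetic EHR generator so every stage can be verified end to end without
access to restricted patient data.

## What it computes

* **CMA7 adherence** — the continuous multiple-interval measure of
  medication availability with carry-over. Each prescription supplies
  `floor(quantity / doses_per_day)` days; a stock process consumes one
  unit per covered day, using oversupply from earlier prescriptions first,
  for prescriptions within and before the 366-day window:

  CMA7 = 100 × covered days / 366,  gap days = 366 − covered days,

  reported continuously and in six categories (≤50, 51–60, …, 91–100).
  The uncapped possession ratio (CMA1) is included as comparator.
* **SABA use** — in-window reliever prescription counts, grouped
  0 / 1–2 / 3–6 / 7–12 / ≥13.
* **Exacerbations** — short oral-corticosteroid courses: prednisolone or
  prednisone at ≥20 mg/day (or tapering) for a respiratory indication,
  with prescriptions ≤14 days apart chain-merged into one course.
* **Asthma control** — ACQ-5 (mean of the first five ACQ items), last 2016
  record or first-quarter-2017 fallback; controlled means score < 0.75.
* **Covariates** — age group, distinct chronic comedications, distinct
  chronic comorbidities, GINA 2016 treatment step from drug type and ICS
  dose (highest prescription of the year).
* **Models** — logistic regression with a normal random intercept per
  practice (lme4), odds ratios with Wald 95% CIs, between-practice
  variance σ², and the latent-threshold intraclass correlation
  ICC = 100·σ²/(σ² + π²/3).

The methods vignette (`vignettes/asthma-adherence-methods.Rmd`) documents
every algorithmic decision, the generator's calibration and its limits.

## Worked example

The `analysis/` scripts run the whole study on a generated cohort
(default: 60 practices, ~4,200 patients; `--full` for the ~13,750-patient
study scale):

```sh
Rscript analysis/01_simulate.R     # write the four routine-care tables
Rscript analysis/02_cohort.R      # selection rules + attrition flowchart
Rscript analysis/03_derive.R      # CMA7, SABA, exacerbations, ACQ, covariates
Rscript analysis/04_models.R      # random-intercept logistic models
Rscript analysis/05_figures.R     # count-plot cross-tabs (optionally --plot)
```

Output of a run with the default seed:

```
attrition (patients remaining after each rule):
  registered_patients        4227
  has_asthma                 4227
  age_ok                     4187
  enough_inhalation_rx       4147
  no_copd                    4066
  computable_ics_duration    4026

analysis dataset: 4026 patients
mean CMA7 62.6% (SD 28.3); 39.8% at <=50%, 29.3% above 90%
mean SABA prescriptions 1.20 (SD 1.73); 13.5% with >=3
12.6% with >=1 exacerbation; ACQ available for 644 patients (50.3% controlled)

any_exacerbation: n = 4009 in 60 practices | sigma2 = 0.247 | ICC = 7.0%
  saba_cat1-2            OR 1.78 (1.42-2.22) p=6.16e-07
  saba_cat3-6            OR 2.92 (2.16-3.94) p=2.6e-12
```

Reading this: 40 patients fall below age 12, 40 lack a second inhalation
prescription, 81 have overlapping COPD, and 40 are dropped because an ICS
prescription's duration is uncomputable. Derived adherence averages 62.6%
with the characteristic U-shaped category distribution (large mass at both
ends). In the exacerbation model, each step up in SABA use raises the odds
of an exacerbation (here OR 1.78 for 1–2 and 2.92 for 3–6 prescriptions vs
none), while 7.0% of outcome variance sits between practices — all at this
cohort size within sampling error of the generator's target values (ICC
6%, OR 1.81 / 2.70).

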