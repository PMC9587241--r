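---
title: "Methods: CMA7 adherence, OCS-course exacerbations and practice-clustered outcome models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CMA7 adherence, OCS-course exacerbations and practice-clustered outcome models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asthmaCMA)
```

`asthmaCMA` implements a prescription-database analysis of asthma controller
adherence and its relation to reliever use and asthma outcomes, of the kind
run on routine primary-care extracts where only issued prescriptions,
coded diagnoses and occasional questionnaires are observed. This vignette
is the package's own account of the models and the design decisions behind
them; the README shows the workflow end to end.

## Data model

Four delimited tables drive everything (see `ehr_schema()`): a patient
registry, ICPC-1 diagnosis episodes, ATC-coded prescriptions, and Asthma
Control Questionnaire (ACQ) records. All date arithmetic is in whole days;
dates are ISO-8601 in files. Drug classes come from a longest-prefix match
of the ATC code against an editable YAML map (`code_config()`): SABA
(salbutamol R03AC02, terbutaline R03AC03), ICS mono (R03BA), fixed
ICS/LABA combinations (R03AK06-11), LAMA (R03BB), oral corticosteroids
(H02AB06/07), other respiratory drugs, and everything else. The shipped
comedication and comorbidity lists and the GINA dose bands are
implementer-chosen defaults: the corresponding source lists are not public,
so no fidelity claim is made for them and they are deliberately easy to
replace.

## Cohort

The analysis window is calendar 2016 (366 days). Practices qualify with at
least 500 patients, at least 46 registration weeks per year and complete
2015-2017 data. Patients enter when they have an asthma episode (R96)
starting on or before the window end, are at least 12 years old in the
window year (window start year minus birth year -- year arithmetic avoids
needing full birth dates), received at least two inhalation prescriptions
(R03A/R03B) inside the window, and have no COPD episode (R95) overlapping
it. Open-ended episodes count as ongoing. Whether the asthma episode must
be *active* in the window rather than ever-recorded is configurable
(`asthma_rule`); the default is the prevalent-or-incident reading, which we
consider the natural one for a chronic relapsing condition recorded as
episodes. Patients with any in-window ICS-containing prescription whose
duration cannot be computed (missing quantity or daily dosing) are excluded
rather than imputed; the rule deliberately applies to ICS-containing
prescriptions only, because only the ICS stream feeds the adherence
measure.

## CMA7 adherence

Adherence to the inhaled-corticosteroid (ICS) controller is the continuous
medication availability variant with carry-over (CMA7): the fraction of
window days on which medication is theoretically available, where
oversupply from earlier prescriptions is consumed before newer supply, for
prescriptions within and before the window.

Each prescription supplies `floor(quantity / doses_per_day)` days (minimum
one day; durations are whole days). Availability follows a stock process:
scanning days chronologically, each prescription adds its duration to a
stock, and every day with positive stock consumes one unit and is covered.
`coverage_days()` implements the equivalent closed form -- event *i*'s
coverage starts at `max(issue_date_i, previous coverage end + 1)` -- which
the test suite proves equal to a literal day-by-day simulation on random
event streams. Then

$$\mathrm{CMA7} = 100 \times \frac{\text{covered days in window}}{366},
\qquad \text{gap days} = 366 - \text{covered days}.$$

Decisions worth making explicit:

* **Lookback.** Carry-over is honoured for prescriptions from 2015-01-01
  onwards (`lookback_start`), one full year before the window; the
  underlying databases guarantee complete data from 2015. Earlier events
  are ignored.
* **Pooling.** All ICS-containing products (ICS mono and fixed ICS/LABA)
  pool into a single supply stream per patient, so switching products
  carries stock over. The analysis computes one ICS adherence per patient;
  a per-molecule treatment would understate availability around switches.
  Whether theoretical use should instead be capped at the prescribed daily
  dose when different molecules overlap is unresolved in the source
  definitions; pooling-with-queueing is our stated choice.
* **Same-day prescriptions** add their durations to the stock (no
  truncation).
* **Categories.** The six printed categories (<=50, 51-60, ..., 91-100) are
  integer labels; the continuous percentage needs half-open bins, so we use
  [0,50], (50,60], ..., (90,100]. A CMA7 of 50.4 therefore falls in 51-60.
* Patients without any ICS-containing prescription (SABA-only, GINA class
  1) have no adherence value at all rather than 0%, and are excluded from
  adherence-dependent models.

`cma1()` (the uncapped medication possession ratio) is provided as a
comparator; for in-window supply CMA7 never exceeds `min(100, CMA1)`.

## Outcomes

**SABA use** is the count of in-window SABA prescriptions, grouped 0, 1-2,
3-6, 7-12, >=13 -- bands aligned with reliever-use guidance (at most 1-2
per year with good control; 13+ marks serious overuse).

**Exacerbations** are proxied by short oral-corticosteroid courses: a
prednisolone/prednisone prescription qualifies when its daily dose
(`strength_mg * doses_per_day`) is at least 20 mg or a tapering scheme was
flagged, *and* it is linked to a respiratory diagnosis (ICPC chapter R,
except COPD) -- or is unlinked while no OCS prescription of that patient
carries a non-respiratory link. The unlinked rule is a literal reading of
"no other known diagnosis for any of their OCS prescriptions"; we treat a
linked R95 like a non-respiratory link. Qualifying prescriptions issued
within 14 days belong to one course. The source definition states the
two-prescription case only; we extend it transitively (chained merging), so
three prescriptions at 14-day steps form one course. The tests prove chain
merging equal to brute-force transitive clustering and monotone in the gap
parameter. Tapering is an explicit boolean in the data model; detecting
tapering schemes from free text is out of scope.

**Asthma control** uses the ACQ: the last record dated in the window, or
failing that the earliest record of the next year's first quarter. The
score is the mean of items 1-5 (symptoms only; the reliever-use item is a
separate model variable, the FEV1 item is stored but unused). The source
phrase "sum score" conflicts with the 0.75 cut-point, which is defined on
the 0-6 per-item scale; we therefore default to the item mean and provide
`mode = "sum"` (with a rescaled cut-point) for sensitivity analysis.
Controlled asthma is a score strictly below 0.75; exactly 0.75 is
uncontrolled. Same-date duplicate records break ties towards the later
input row.

## Covariates

Age groups are the closed bins 12-17, 18-39, 40-54, 55-64, 65+.
Comedication counts *distinct* listed ATC codes prescribed in the window
(a number of medications, not of prescriptions); comorbidity counts
distinct listed ICPC codes with an episode starting on or before the window
end (chronic conditions are treated as ongoing); both are grouped
0/1/2/>2. GINA 2016 treatment steps are assigned per prescription --
SABA-only 1, low-dose ICS 2, low-dose ICS/LABA 3, medium/high-dose ICS or
ICS/LABA 4, add-on treatment (LAMA, biologics) 5 -- and the patient takes
the maximum step over the year, i.e. the prescription with the highest ICS
dose. ICS mono plus a separate in-window LABA counts as a combination.
Dose banding needs `strength_ug`; events lacking it are step-undetermined,
and a patient is undetermined only if every event is.

## Outcome models

Both outcomes (any exacerbation vs none; controlled vs uncontrolled
asthma) are modelled with logistic regression with a normal random
intercept per general practice, estimated by maximising the approximate
marginal likelihood (Laplace; `lme4::glmer`). We checked on this design --
roughly 200 practices of 70 patients -- that adaptive Gauss-Hermite
quadrature moves the variance estimate by about 1%, so the faster Laplace
fit is the default. Fixed effects are the adherence category, SABA
category, sex, age group, comedication, comorbidity and GINA class, each
referenced at the most favourable level (91-100% adherence, 0 SABA, male,
12-17, 0, 0, class 2). Odds ratios carry Wald 95% intervals on the
log-odds scale; no multiple-testing correction is applied. The
between-practice variance $\sigma^2$ is reported with the latent-threshold
intraclass correlation

$$\mathrm{ICC} = 100 \cdot \frac{\sigma^2}{\sigma^2 + \pi^2/3},$$

the only convention under which a variance of about 0.2 corresponds to an
ICC of about 6%. Group comparisons in the descriptive table use Pearson
chi-square tests without continuity correction.

## The synthetic EHR generator

Real extracts of this kind are access-restricted, so the package ships a
generator (`generate_ehr()`) whose defaults *are* the study conditions:
about 200 practices with on average 68.8 analysable patients
(about 13,760), covariate marginals equal to the published descriptive
distribution, outcome-model coefficients equal to the published odds
ratios with between-practice variances 0.21 (exacerbation) and 0.10
(control), and an ACQ availability of 2183/13756. Model intercepts are not
free parameters: `calibrate_intercept()` solves for the intercept that
reproduces the published marginal rates (13.15% any exacerbation; 50.8%
controlled among ACQ respondents) by exact enumeration of the independent
covariate-level combinations and mid-quantile integration of the practice
intercept.

Two components were calibrated once, then frozen:

* the **SABA count model** draws the printed five-category distribution
  and fills in within-category counts (a two-point split on 1-2, truncated
  geometric decay inside 3-6 and 7-12, 13 + Poisson above) whose parameters
  are solved in closed form so the expected count is 1.20 per patient;
* the **adherence mixture** draws a latent implementation level
  $a \in [0,1]$ from a six-component mixture with the printed category
  proportions as weights; the within-component uniform ranges were tuned in
  one calibration pass against the *derived* CMA7 distribution -- refills
  every $\approx D/a$ days (supply $D = 30$ days, multiplicative log-normal
  jitter, SD 0.15, mean-corrected) plus day rounding and carry-over shift
  the derived value relative to $a$ -- so that the pipeline reproduces the
  printed category distribution and the 62% mean.

Refill streams start near the window start (30% of patients instead get a
late-2015 first fill, exercising pre-window carry-over), and at least two
in-window fills are forced (the cohort criterion). Exacerbations are
emitted as 1-2 qualifying prednisolone prescriptions (30 mg/day, linked
R96, occasionally unlinked) within 14 days per course, with courses spaced
more than 30 days apart; ACQ items are drawn conditional on the true
control status (item-1..5 mean below vs at/above 0.75). SABA counts,
course counts, control status, comedication, comorbidity, GINA class and
age group therefore round-trip through the pipeline *exactly*, while the
adherence category is deliberately recovered with noise: outcome models are
generated on the true levels, so model recovery through the derived
categories measures the whole pipeline including the attenuation that CMA7
estimation induces on the adherence coefficients. SABA coefficients are
the clean recovery targets. Small decoy fractions (COPD overlap, age
below 12, a single prescription, a missing-dose ICS prescription) verify
that each selection rule removes exactly its targets.

What the generator does *not* emulate: seasonality, molecule-level
prescribing fashion, dose changes within the year, informative ACQ
availability (a biased-availability mode is not provided; availability is
missing completely at random), practice switching, and correlation between
covariates (levels are drawn independently). Passing recovery tests
therefore shows the algorithms and models are implemented correctly under
the stated generative assumptions -- not that real routine-care data meet
those assumptions.

## Numerical choices and degenerate inputs

Durations floor to whole days with a minimum of one day; stock is integer.
Coverage is O(events) per patient via the closed form. Empty ICS streams
yield a flagged 0% CMA7 internally and an `NA` adherence value in the
dataset. A zero contingency margin is an error (expected counts
undefined), as is a single-practice model (variance unidentifiable).
Intercept calibration uses 101 mid-quantile nodes for the random-intercept
integral; the calibration unit test bounds the resulting marginal-rate
error well below Monte-Carlo noise at the study scale.

## Problem sizes used in verification

The test suite runs oracle-equivalence sweeps at 1,000 random cases each,
module checks on cohorts of 15-60 practices, a 12-replicate
confidence-interval coverage study at 40 practices x 55 patients (the
pooled-coverage binomial bound replaces a much larger replicate count; at
these sizes the coverage statistics are already informative), and one
full-scale end-to-end recovery on the default ~13,750-patient cohort.
These sizes are the package's choice of desk-scale verification; the
generator accepts arbitrary sizes.

## Known limitations

The adherence measure is availability, not intake: overuse is invisible
and carry-over assumes prescribed-dose consumption. OCS-course
exacerbations capture mild-to-moderate events only. The shipped code lists
and dose bands are defaults, not the (unpublished) originals. GINA class-1
patients carry no adherence value and drop out of the outcome models, so
estimates condition on ICS use.
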