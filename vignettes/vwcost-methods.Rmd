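---
title: "Methods: virtual-ward cost-comparison modelling with vwcost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual-ward cost-comparison modelling with vwcost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vwcost)
```

## The problem and the model

A virtual ward (VW, "hospital at home") treats patients who would otherwise
occupy an acute bed, either by avoiding an admission entirely (*step-up*) or
by discharging an inpatient early and finishing treatment at home
(*step-down*). `vwcost` implements a cost-comparison model — deliberately
*not* a budget-divided-by-activity calculation — that attaches unit costs to
each patient's resource use and compares the result with the standard-care
(SC) counterfactual: the inpatient pathway in the absence of the VW, with
resource-use rates taken from a propensity-matched control group.

Key modelling assumptions:

* **30-day horizon.** Costs and resource use are attributed to a VW episode
  for 30 days from discharge (day 0 = discharge day, boundary inclusive);
  later events are considered unrelated. The horizon is configurable
  (`horizon_days`).
* **Annual extrapolation.** Cohort-level totals observed over
  `observed_months` are scaled by `12/observed_months` (default: 6 months,
  factor 2). Patient records are never duplicated; only totals and the cohort
  size scale.
* **Counterfactual conventions.** Every step-up patient is assumed to have
  needed an inpatient admission (full non-elective admission cost, £2587, in
  the SC arm). A step-down patient's avoided hospital days enter as a
  *negative* VW-arm component (bed-days saved × excess-bed-day "hotel" cost,
  £338/day), not as a positive SC cost; the SC column for that component is
  zero. This sign convention reproduces the published per-patient
  decomposition cell-for-cell.
* **Equal cost sharing.** Annual fixed costs (monitoring platform, overheads,
  licences, pharmacy, leadership, programme management — carried as a single
  aggregate of £308,113 because no itemization is published) and the one-off
  set-up cost (£4685) are shared equally across the annualized patient volume.
* **No discounting** (horizon ≤ 1 year) and **no currency conversion** (GBP
  only). Fiscal years are opaque labels; `inflate_cost()` applies a
  user-supplied index ratio (e.g. PSSRU) for users whose base-year costs
  differ; the shipped excess-bed-day cost is stored already inflated to
  2021/22.

## Staff microcosting

The cost of a timed activity is *duration × cost-per-minute*, with a role's
cost per minute equal to its total annual employment cost (wages, oncosts,
qualifications, overheads — the PSSRU convention) divided by annual working
minutes (PSSRU working hours: 1553 h/year for a nurse, 2142 h/year for a
consultant). Published sources often state only a blended per-minute rate for
an activity ("Bands 5 or 7, £1.02/min") without the underlying staff
proportions; the shipped profiles therefore carry the published blended rates
as overrides (home visit: 45 min × £1.02 = £45.90; routine call: 10 min ×
£1.79 = £17.90), and the staff-mix mechanism exists for services that know
their proportions. We deliberately do not invent a mix the source does not
state. The annual salary totals in the default configuration are illustrative
PSSRU-2023-like values and are *not* used by the default profiles.

Two home-visit prices coexist in the published inputs: the national reference
cost (£102/visit) and the microcosted £45.90. The default is the microcosted
rate (`visit_costing = "microcosted"`), which is consistent with the
published per-patient visit component; `"reference"` selects £102.

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `horizon_days` | 30 | days | standard NHS outcome window for an admission |
| `observed_months` | 6 | months | published observation window; ×2 annualization |
| `n_patients` | 324 | patients | half-year cohort → 648/year |
| `step_up_proportion` | 0.45 | — | derived: 1164/2587 (see calibration) |
| `dsa_fraction` | 0.15 | — | published one-way variation range |
| admission cost | 2587 | GBP | NEL HF/shock reference cost 2021/22 |
| excess bed day | 338 | GBP/day | 2017/18 reference cost inflated to 2021/22 |
| `bed_days_saved_step_down` | 3.00 | days | derived: (558/338)/0.55 |
| `poc_test` unit cost | 24.50 | GBP | package estimate (see below) |

## Calibration of the synthetic generator

No patient-level data are distributed, so the generator emulates the
published cohort. Event rates are back-derived with `calibrate_rates()` as
*published per-patient component cost ÷ unit cost*:

* VW arm: readmission probability 326/2587 ≈ 0.126, ED probability 14/158,
  NHS 111 rate 1/11, home visits 154/45.90 ≈ 3.36/patient, calls
  140/17.90 ≈ 7.82/patient.
* SC arm: readmission 556/2587 ≈ 0.215, ED 19/158, outpatient 117/213,
  NHS 111 1/11.
* The step-up proportion 1164/2587 ≈ 0.45 is implied by the initial-admission
  component; it is a derived calibration, not a published fact. Bed-days
  saved per step-down patient, (558/338)/(1−0.45) ≈ 3.00, follows from the
  same split.
* The point-of-care unit cost is not published (only the £98/patient
  component); the default £24.50/test (an iSTAT cartridge plus handling,
  flagged `synthetic` in its provenance tag) implies 4 tests/patient. Any
  pair with the same product reproduces the component mean.

Counts (visits, calls, POC tests, NHS 111, outpatient) are Poisson at the
configured mean — the published tables report only means, so a
single-parameter count model is the honest choice; ED attendance and
readmission are Bernoulli. Ages are truncated-normal (mean 78, SD 10, bounds
40–100 — a realistic acute HF cohort), gender is Bernoulli(0.45 female), and
diagnoses are drawn from three I50.x codes. Every admission lasts ≥ 1 day
(LOS = 1 + Poisson(6)), so each generated patient is onboarded exactly once —
see the equipment-cost note below.

**Horizon semantics.** Configured rates are *within-horizon* (30-day)
expectations, because that is what the published per-patient components
measure. Event days are uniform on 0–45 so that roughly a third of drawn
events fall beyond the horizon and exercise the filter; drawn totals are
inflated by (45+1)/(30+1) so the post-filter empirical rates converge to the
configured values. This choice was fixed before any acceptance measurement.

**What a green test establishes — and what it does not.** The generator
reproduces the *means* of the published cohort under independence across
patients and event types. Real data have correlated events (a readmitted
patient attends ED more), overdispersed counts, seasonal referral mixes and
acuity drift — none of which are emulated. A passing pipeline test therefore
validates the costing arithmetic and calibration, not the clinical claim.

## Matching

The published analysis propensity-matched controls 1:1 on age, gender and
ICD-10 primary diagnosis but does not state the algorithm, replacement
policy or caliper. `vwcost` uses the most common reproducible baseline:
logistic scores, greedy nearest-neighbour matching without replacement,
treated processed in descending score order, no default caliper, diagnosis
as categorical indicators at full-code granularity (3-character truncation
via `truncate_icd10`). All are exposed so users can vary them; exact
reproduction of the original pairs is impossible and not attempted. Perfect
separation makes logistic scores degenerate, so it is rejected with advice
to match exactly on the offending covariate. Ties in score distance are
broken by input order, making matching deterministic given a fixed input
ordering.

The matched control's resource use is costed under the *treated* partner's
pathway label, because step-up/step-down is a VW-side construct: the
counterfactual of a step-up patient includes the initial admission.

## Numerical and accounting choices

* All currency is held at full double precision; rounding (half away from
  zero, the convention of financial tables) happens only in report writers.
  Published-table checks that are rounding-sensitive are asserted at ±£2,
  matching the tables' own "totals may not match exactly due to rounding".
* Accounting identities are exact by construction: per-patient overall =
  direct + indirect = sum of components; population total = set-up + fixed +
  variable; per-patient total = population / cohort size.
* **Equipment costs and the zero-stay episode.** The home-monitoring (£34)
  and home-set-up (£30) components are charged once per episode *with a
  positive VW length of stay*: equipment is delivered when a patient is
  onboarded. A degenerate zero-stay, zero-event episode therefore costs only
  the shared platform and set-up base — the behaviour the per-patient costing
  contract requires — while the generator's LOS ≥ 1 guarantees the published
  per-patient means reproduce exactly.
* The one-way DSA and break-even analyses run on the deterministic
  expected-cost evaluation (`expected_costs()` over `model_params()`), not on
  Monte-Carlo replicates: the underlying model is deterministic given rates,
  and this keeps tornado bars free of simulation noise. DSA ties in spread
  are broken lexicographically for stable output.
* Break-even: smallest integer `n ≥ 1` with `S + F + n·v ≤ n·c`, i.e.
  `⌈(S+F)/(c−v)⌉`, unreachable when the net variable saving `c−v ≤ 0`. With
  the default inputs this gives **194 patients/year**. The published
  evaluation reports 185; that figure is not recoverable from the published
  aggregates (recomputation gives ≈190–194 depending on whether set-up is
  included), so the package asserts the closed form against a brute-force
  scan rather than the printed number.

## Known limitations

* Independence and equidispersion in the generator (above).
* Admission and excess-bed-day costs are scalars, not an HRG tariff engine;
  acuity case-mix is not modelled.
* The SC arm inherits the treated pathway mix rather than modelling
  admission decisions; this mirrors the published counterfactual assumption
  that all step-up patients would otherwise have been admitted, which the
  original authors themselves flag as a judgement subject to selection bias.
* Fixed costs are a single aggregate; per-category sensitivity analysis of
  fixed costs therefore varies the aggregate.
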