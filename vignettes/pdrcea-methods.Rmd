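---
title: "Model and methods behind pdrcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind pdrcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdrcea)
```

## The decision problem

Proliferative diabetic retinopathy (PDR) can be treated with panretinal
photocoagulation (PRP) — cheap, durable, but capable of causing a permanent
peripheral visual field defect (pVFD) and contributing to diabetic macular
edema (DME) — or with intravitreal anti-VEGF injection, which spares the
peripheral retina but is expensive, must be repeated, and carries a small
endophthalmitis risk. `pdrcea` implements a Markov cohort model comparing
four treatment strategies for a cohort of 50-year-old PDR patients followed
until age 100:

* **prp-only** — PRP at every treated PDR cycle;
* **antivegf-only** — anti-VEGF at every treated PDR cycle;
* **prp-first** — PRP first-line; after a treated-and-failed cycle,
  anti-VEGF thereafter;
* **antivegf-first** — the reverse.

Outcomes are discounted lifetime cost, from three perspectives (payer:
insurance-covered medical cost; healthcare: covered plus non-covered
medical cost; societal: healthcare plus transportation, patient time, care,
and low-vision-aid costs), and discounted quality-adjusted life years
(QALYs). The decision outputs are incremental cost-effectiveness ratios
(ICERs) against PRP-only, an efficiency frontier, one-way sensitivity
(tornado) analyses, and probabilistic sensitivity analysis (PSA) with
cost-effectiveness acceptability curves (CEACs).

## State space

The clinical states are NPDR (non-proliferative retinopathy, i.e.
remission after successful PDR treatment), PDR, DME, SVL (severe visual
loss, visual acuity < 0.1), and death. To keep the dynamics Markovian the
clinical states are expanded by attributes:

* *therapy line* (first/second) — which PDR therapy the strategy will use
  next;
* *last therapy* — the therapy that induced the current remission; it sets
  the PDR recurrence probability from NPDR and is carried through
  NPDR-origin DME states;
* *ever-PRP* — once PRP has been administered the pVFD disutility applies
  for life;
* *DME origin* — successful DME treatment returns the patient to the state
  the edema arose from;
* *SVL tenure* (years 1–5, 5+) — tunnel states making the declining
  injection-continuation probability in SVL duration-dependent.

`build_state_space()` closes over the reachable combinations per strategy
(11–23 states plus death): single-line strategies never reach second-line
states and the anti-VEGF-only strategy never reaches post-PRP states.

## Cycle dynamics

Each annual cycle applies, in order: death (age-specific baseline
probability times a diabetes mortality relative risk of 1.49, times 11.54
for SVL occupants, capped at 1); then, among survivors:

* **PDR** occupants are treated with the current line's therapy with
  probability 0.8 (20% loss to follow-up, redrawn each cycle). Success
  (0.2008 for PRP; ×1.75 for anti-VEGF, capped at 1) moves them to NPDR.
  Failed or untreated occupants face the annual SVL (0.18) and DME (0.179)
  risks as competing exits. In two-line strategies a treated-and-failed
  cycle switches the line; an untreated cycle does not, since no therapy
  failed.
* **NPDR** occupants recur to PDR (0.0169 after PRP; ×1.15 after
  anti-VEGF) or develop DME (0.1522).
* **DME** occupants receive three anti-VEGF injections and resolve back to
  their origin state with probability 0.534.
* **SVL** occupants remain (tenure advancing) and receive two injections
  per year scaled by the tenure-year continuation probability
  (0.914, 0.736, 0.650, 0.609, 0.537, then 0.481).
* Endophthalmitis is not a tracked state: each injection adds a
  0.0006 × (1 − 0.595) probability of transition to SVL (incidence times
  failed treatment) and an expected treatment cost of incidence times the
  episode cost.

Rewards (costs and utility) accrue on the state occupied at cycle start;
there is no half-cycle correction, and cycle *t* is discounted by
(1 + 0.045)^−t with the first cycle undiscounted. Both conventions are
deliberate and recorded in report metadata; `cohort_settings()` exposes
the exponent offset for sensitivity checks. Costs and effects share the
single 4.5% annual discount rate.

State utilities decline linearly with age from the upper end of each
state's published range at age 50 to the lower end at age 100; all four
states share a span of exactly 0.055, so each state is parameterised by
its age-50 value (NPDR 0.904, PDR 0.901, DME 0.912, SVL 0.851) minus a
common fixed span. The pVFD disutility (0.01) applies additively and
permanently after any PRP administration, floored at zero. Care cost
($11,826/yr, societal perspective) accrues in SVL only below age 90,
reflecting the assumption that everyone needs daily-living assistance
from 90 regardless of vision.

## Mortality

No national life table is printed with the parameter set, so the default
baseline is a Gompertz stand-in, `q(x) = 1 − exp(−a·e^{bx})` with
`a = 2.8e−5`, `b = 0.09`, calibrated to plausible East-Asian adult
mortality (q(50) ≈ 0.0025, q(80) ≈ 0.037). Any two-column `age,q` CSV can
replace it via `read_life_table()`. Relative risks multiply the annual
probability directly (not via rate conversion) and are capped at 1; the
SVL relative risk multiplies the already diabetes-adjusted probability,
reading the published contrast as SVL vs non-SVL within the diabetic
cohort. All mortality-dependent absolute results inherit the stand-in's
approximation.

## Parameters and sensitivity ranges

`default_parameters()` returns every parameter with its base value,
deterministic-sensitivity bounds, and PSA family. Bounds are ±20% of base
except for relative risks, which use their published 95% CIs; the SVL
mortality relative risk (11.54) has no published CI, so it keeps the ±20%
band. Probability bounds are capped at 1; utility bounds may exceed 1 and
are censored at use, mirroring the published censoring rule for sampled
utilities.

PSA families follow the published table: beta for probabilities, gamma for
costs, lognormal for relative risks, triangular for the PDR→SVL
probability, loss to follow-up, and utilities. The table names families
but no dispersion, so beta and gamma are fit by the method of moments with
mean equal to base and standard error 0.2·base/1.96 — the ±20% band read
as a 95% interval. Lognormal uses μ = ln(base) and
σ = (ln hi − ln lo)/(2·1.96) from the CI. Draws are independent across
parameters (no correlation structure is published); out-of-domain draws
are rejected and redrawn so the stated family is preserved, except
utilities, which are censored at 1. The SVL continuation vector, the
discount rate, and the pVFD disutility are fixed in PSA (their printed
distribution is "NA") while keeping deterministic ranges. All of these
dispersion choices are assumptions, flagged as such.

## Economics

`incremental_vs_comparator()` mirrors the published table layout: every
strategy against PRP-only, with the ICER reported only when both
increments are positive, "cost-saving" when cost falls without losing
QALYs, and "dominated" for the reverse. ICERs are kept unrounded
internally; `format_incremental()` rounds only for display, which is why a
quotient of rounded increments can differ from an internally computed
ICER. `efficiency_frontier()` additionally provides the standard
sequential frontier with strict and extended dominance, and `nmb()` the
net monetary benefit WTP·QALY − cost used as the CEAC optimality rule
(maximal NMB per draw, ties split equally) — the conventional resolution
of the looser "most effective within a threshold" phrasing. The default
WTP grid, $0–100,000 in $1,000 steps, covers the published $24,400/QALY
threshold with room above it.

## Synthetic data

The study's raw inputs (national claims data for macro-costing, a 300
patient EQ-5D survey, the national life table) are not public, so the
package ships generators that emulate their *structure*:

* `synth_claims_episodes()` — one record per patient-year and state, each
  cost component gamma-distributed around the published means with a
  coefficient of variation of 0.8 (a configurable stand-in; real claims
  dispersion is unknown). `macro_costing()` recovers cost per state-year.
* `synth_eq5d_survey()` — beta-distributed utility responses (SD 0.08,
  again configuration, not an estimate) recovered by
  `estimate_state_utilities()`.
* `gompertz_life_table()` — the mortality stand-in above.

Recovery tests therefore certify the estimators against the synthetic
truth, not against the study's data: passing them shows the macro-costing
and survey pipelines are unbiased at the stated sample sizes, nothing
more.

## Numerical choices and test scale

Transition rows are validated to sum to 1 within 1e−12; cohort occupancy
conserves mass within 1e−10 over all 50 cycles. The cohort engine is
validated against an independent 50,000-patient microsimulation (3
Monte-Carlo-SE agreement per strategy and outcome, with an independent
replicate required before a single excursion counts as disagreement). The
frontier is checked against brute-force net-benefit enumeration on 1,000
random instances. The test suite runs the PSA at 2,000 draws (the package
default for reports; 10,000 is recommended for publication figures) and
property checks at 1,000 random parameter sets — sizes chosen to make the
suite a routine desk run while keeping Monte-Carlo error well below the
tolerances tested.

## Design decisions taken where the source was open

* DME resolution returns patients to the state that generated the edema;
  the alternative (always NPDR) would silently cure PDR.
* The 0.18 PDR→SVL risk applies only to occupants not cured that cycle;
  applying it to the newly cured would double-count failure.
* Line switching happens after one treated-and-failed cycle.
* Anti-VEGF dosing: three injections per treated year in PDR and DME
  (generalising the loading-dose regimen), two per year in SVL.
* Low-vision glasses are a societal cost (a non-medical aid, like care
  cost); covered/non-covered medical components define the payer and
  healthcare perspectives.
* Deaths, then disease transitions; no direct NPDR→SVL or DME→SVL
  pathways besides injection-related endophthalmitis.

## Known limitations

The model is monocular and annual-cycle; treatment schedules finer than a
year, binocular asymmetry, and adaptive strategies beyond the four listed
are out of scope. Absolute cost and QALY totals depend on inputs that are
not published — the national life table, the cycle-accounting conventions
of the original software, injection frequency outside SVL, and the DME
resolution destination — so they should be read as internally consistent
model outputs, not as a reproduction of the published totals; the
acceptance checks treat the published table as an arithmetic oracle for
the economics layer and as a qualitative anchor for model behaviour.
Lifetime SVL and DME exposure is particularly sensitive to the annual
0.18 PDR→SVL and 0.1522 NPDR→DME probabilities compounding over decades,
which materially shapes the relative economics of the strategies.
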