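---
title: "A Markov cohort model of adjuvant chemotherapy for colon cancer in South Africa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of adjuvant chemotherapy for colon cancer in South Africa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coloncea)
```

## The decision problem

After curative resection of high-risk stage II or stage III colon cancer,
South African public-sector patients may receive capecitabine plus
oxaliplatin (CAPOX) for 3 or 6 months, single-agent capecitabine for
6 months, or no adjuvant therapy. `coloncea` implements a decision-analytic
Markov cohort model that compares the lifetime discounted societal cost and
disability-adjusted life years (DALYs) of these four strategies, reports
incremental cost-effectiveness ratios (ICERs) in 2021 international dollars
(I$) per DALY averted against a willingness-to-pay (WTP) threshold of
I$13,764 (the 2021 South African GDP per capita), and quantifies
uncertainty through deterministic, probabilistic, subgroup and scenario
analyses.

## Model structure and assumptions

A closed cohort (base case: 60-year-olds) starts disease-free
post-resection and is simulated in monthly cycles for
`min(300, 12 * (85 - start_age))` cycles. States:

* **Disease-free.** Subject to monthly recurrence (from the strategy's
  calibrated schedule) and background mortality (from the life table).
  Colon cancer death is not reachable from this state.
* **Recurrence.** All recurrences are treated as clinically distant
  metastases. At entry, one third are liver-only and one third of those
  (1/9 overall) undergo curative-intent hepatectomy; everyone else starts
  first-line palliative chemotherapy and moves to second line after the
  first-line duration (6 months by default), with at most two lines per
  patient. The recurrence state is a *tunnel*: occupancy is indexed by
  months since recurrence so post-recurrence mortality can be time-indexed.
  Post-recurrence survival is stratified by the initial adjuvant arm
  (doublet versus single agent or none); the second stratum is derived from
  the first through a proportional-hazards adjustment with hazard ratio
  1.61. Hepatectomy patients incur the one-time procedure cost but follow
  the same post-recurrence survival stratum as their arm, because no
  separate post-hepatectomy curve is available.
* **Death from colon cancer** and **death from other causes**, both
  absorbing.

**Within-cycle competing risks.** The ordering is fixed and documented:
background death is applied first, then recurrence to the survivors, i.e.
`P(recurrence this cycle) = (1 - p_death_other) * p_recur`; from the
recurrence state, background death precedes cancer death. This specific
ordering makes the disease-free occupancy factor exactly as
`S_background(t) * S_curve(t)`, so the internal-validation round trip
(below) is exact by construction. New recurrences are not at risk of death
in their entry cycle; the test-suite microsimulation oracle applies the
same convention.

**Half-cycle correction.** State time per cycle is trapezoidal: the mean of
the occupancy at the cycle's start and end boundaries. It applies to
overall survival, per-state-time costs and disability time. One-time
transition costs (hepatectomy, metastatic course starts, surveillance
visits) attach to their entry boundary and are not half-cycle corrected.

## Calibration

`curve_to_monthly_probs()` converts a survival curve to monthly
probabilities through the discrete-hazard identity
`p[t] = 1 - S(t+1)/S(t)`, after resampling the curve onto the monthly grid
by linear interpolation of log-survival (exact for exponential segments;
the original analysis does not state its interpolation, so the choice is
made here and documented). Recurrence schedules are truncated to
probability 0 beyond the last observed curve time, mirroring the
disease-free-survival plateaus of the source trials, rather than
extrapolated. Background mortality uses the abridged life-table band
containing the exact fractional attained age, converted by
`1 - (1 - q)^(1/12)` so twelve cycles compound back to the annual
probability; no smoothing is applied between bands.

**Internal validation.** `validate_dfs()` compares model disease-free
survival at 60 months against the calibration curve, after dividing the
disease-free occupancy by the cumulative background-mortality-only survival
so that mortality added by the model does not contaminate the comparison
(the alternative denominator `1 - DEAD_OTHER` is available but is slightly
contaminated by competing mortality inside the recurrence state). The
analysis' own standard is a relative error below 1.5% for every strategy
and stage; with schedules derived from the shipped curves the error is at
machine precision.

## Economics

* **Discounting.** 5%/year, annual-equivalent compounding: a flow at month
  *m* is discounted by `(1 + r)^(-m/12)` (the simple `r/12` monthly rate is
  rejected because it does not reproduce an exact annual 5%). State-time
  flows are discounted at mid-cycle, one-time flows at their entry
  boundary; a rate of 0 reproduces undiscounted sums exactly.
* **Costs** are societal, in 2021 ZAR (authoritative) converted to I$ at
  the 2021 purchasing-power parity of 7.097 ZAR/I$, unrounded internally
  and rounded half-up for display. The adjuvant course cost is spread
  uniformly over the treatment months and accrues on disease-free state
  time; metastatic course costs attach at line entry; acute adverse-event
  costs attach at model start with regimen-specific per-course incidence;
  residual neuropathy accrues an annuity over the 36 months post-treatment;
  surveillance items follow a documented visit calendar; indirect costs
  (transportation plus lost wages) accrue per visit-day — CT per patient,
  colonoscopy and treatment months per patient plus one caregiver.
* **DALYs** = YLL + YLD, discounted, without age weighting. The YLL
  convention follows the source parameterisation: time spent in the colon
  cancer death state *within the horizon* accrues at weight 1, while
  all-cause death accrues nothing. This differs from the GBD
  standard-life-expectancy formula and changes DALY magnitudes, so it is
  called out prominently. YLD accrues recurrence state time at annual
  weight 0.451 plus adverse-event disability (one month per acute event;
  36 months for residual neuropathy).
* **Frontier.** Strategies are cost-sorted (ties broken by higher
  effectiveness), weak dominance is marked, sequential ICERs are computed
  along the remaining chain, and extended dominance removes strategies
  whose sequential ICER exceeds the next-costlier one. Reported ICERs are
  deliberately *not* recomputed after extended-dominance removal — the
  only convention consistent with the published stage II CAPOX 3-month
  ICER of 250 (recomputing against the reference gives 629). Both
  conventions are implemented (`recompute_extended`). The recommendation
  is the costliest frontier member with ICER at or below WTP, and is
  cross-checked against the NMB-maximising rule in the tests.

```{r frontier-demo}
ref <- reference_base_case()
d <- ref[ref$stage == "HIGH_RISK_II", c("strategy", "cost_int", "dalys_averted")]
names(d)[2] <- "cost"
frontier(d, wtp = 13764)
```

## Sensitivity analyses

**Deterministic.** Probabilities are swept -25%/+25% and costs -50%/+100%
as hazard-scale or cost multipliers, the discount rate absolutely over
0–0.10, and the recurrence disability weight over its published 0.307–0.600
range. Whole schedules are perturbed by one scalar hazard multiplier per
draw rather than per-cycle independent draws, keeping curves coherent. The
willingness-to-pay is excluded from the tornado because varying it cannot
move an ICER; it enters through the recommendation threshold and the PSA
grid. `threshold_multiplier()` finds the multiplier at which a pairwise
ICER crosses the WTP by bisection to relative tolerance 1e-4 and reports
"no threshold" rather than erroring when there is no crossing.

**Probabilistic.** Each iteration makes one joint draw — beta-distributed
probability references (sd 10% of base) applied as shared hazard-scale
multipliers, gamma cost multipliers (sd 25%), PERT disability weights over
their published ranges — runs all strategies deterministically, and records
the NMB-maximal strategy on a WTP grid from one-half to three times the
base threshold. The published analysis used 100,000 iterations; the
package's desk default is 5,000 and the test suite uses 60–200, which is
enough to check reproducibility, CEAC mass conservation and agreement of
the modal strategy with the deterministic recommendation. A single seeded
RNG stream drives the whole run (R has no cheap independent substream API;
the seed and iteration count are recorded in the result, which keeps runs
bit-reproducible).

**Subgroups.** The published subgroup recurrence inputs are in unpublished
supplements, so `subgroup_multipliers()` ships synthetic stand-ins chosen
a priori on clinical grounds: high-risk subgroups (stage II T4; stage III
T4 or N2) carry elevated recurrence hazards with a relatively smaller
multiplier on the CAPOX 6-month arm, reflecting the duration-by-risk
interaction reported by the adjuvant-duration trials; low-risk subgroups
scale all arms equally below 1. `subgroup_model()` accepts arbitrary
per-strategy multipliers so real values can be substituted. On the shipped
fixtures the high-risk subgroups escalate the recommendation from CAPOX
3 months to CAPOX 6 months and the low-risk subgroups do not — the same
qualitative pattern as the published analysis.

**Scenario.** `scenario_xeliri()` swaps every FOLFIRI metastatic line to
XELIRI (cost only; effectiveness is assumed equivalent). On the fixtures
the recommendation remains CAPOX 3 months for both stages.

## What the synthetic data do and do not represent

The recurrence inputs of the original analysis are digitized
Kaplan–Meier traces that were never deposited. The generator therefore
builds *range-calibrated Weibull* curves: shape and scale are solved so the
month-0 and final-month monthly probabilities equal the printed per-month
range endpoints for each stage and strategy, giving a rising-then-exhausted
recurrence hazard over the 60-month support. The implied 5-year
disease-free survival values are fixture properties (they happen to land
close to the trial values — e.g. 0.87 for CAPOX 3 months in high-risk
stage II), but they are not the trial values, and the printed ranges
themselves leave the true time profile unidentified. Post-recurrence
survival uses an exponential doublet stratum with an 18-month median — a
value chosen once as representative of the 1998–2003 registry era that
anchors the stage III stratum — and the hazard-ratio-1.61-adjusted
single-agent/none stratum. Adverse-event incidences, the surveillance
calendar and the life table are documented synthetic fixtures of realistic
magnitude. Consequently the absolute costs, survival and DALY outputs on
fixtures are *not* reproductions of the published absolute values; what the
passing tests establish is the model mechanics (conservation, oracle
equivalence, calibration round trips, discounting and DALY arithmetic),
the frontier logic on the published cost/effect pairs, and the qualitative
structure (arm ordering, subgroup escalation, scenario stability).

The printed per-month ranges also force one structural quirk: the
capecitabine stage III range starts *below* the CAPOX 6-month range, so no
generator honouring the ranges can keep the arms ordered pointwise in
hazard at every month. The cross-arm ordering invariant is therefore
asserted on 5-year cumulative survival, where it holds.

One direction was genuinely ambiguous in the source: the hazard ratio 1.61
is attached to the capecitabine/no-adjuvant post-recurrence rows, yet the
discussion text describes *improved* survival in those arms. The generator
follows the operation contract (the single-agent/none stratum is the
hazard-adjusted, lower-survival stratum); passing `hr_single_or_none < 1`
flips the direction without code changes.

## Numerical choices and degenerate inputs

* Probabilities are validated at load (`transition_schedules()`, the CSV
  readers), never mid-run; post-recurrence and background schedules
  shorter than the horizon raise an error naming the schedule and the
  deficit, while recurrence schedules are zero-padded (risk exhausted).
* Curves reaching zero survival terminate their probability sequence with
  a final probability of 1; flat curves give all-zero schedules.
* Occupancy rows sum to 1 within 1e-9 over the full horizon; absorbing
  occupancies are non-decreasing.
* Frontier ties in cost are broken by higher effectiveness (reported via a
  message); exact duplicates keep their first occurrence.
* Beta/gamma moment matching and PERT bounds are validated when the
  distribution is specified, so infeasible sensitivity configurations fail
  before any iteration runs.

## Problem sizes

The shipped analyses run at desk scale by design: 300-cycle horizons with
300-deep tunnels (a few milliseconds per strategy), 8 stage-by-strategy
calibration validations, a 200,000-patient microsimulation oracle for the
engine-equivalence check, and PSA runs of 60–5,000 iterations. All were
chosen as the smallest sizes at which the corresponding check is
statistically meaningful.

## Limitations

Fixture-dependent quantities (absolute costs, the PSA optimal fractions,
tornado threshold percentages) cannot reproduce the published numbers
without the unpublished digitized curves and visit schedules; they are
covered by directional assertions instead. The model excludes biologic
agents in the metastatic setting, rectal cancer, and external validation
against the local prospective cohort (data not available). QALYs,
age-weighted DALYs and budget-impact analysis are out of scope.
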