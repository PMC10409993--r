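---
title: "Methods: a three-state cost-effectiveness model of first-line cemiplimab plus chemotherapy in advanced NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-effectiveness of cemiplimab plus chemotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsclcCEA)
```

## The decision problem

Cemiplimab, an anti-PD-1 antibody, added to platinum-doublet chemotherapy
(the CCT strategy) prolongs overall survival (OS) and progression-free
survival (PFS) in untreated advanced non-small cell lung cancer relative
to chemotherapy alone (PCT): trial medians 21.9 vs 13.0 months OS
(hazard ratio 0.71) and 8.2 vs 5.0 months PFS (hazard ratio 0.56). The
package asks whether that benefit is worth its price from the Chinese
healthcare payer perspective, using a willingness-to-pay (WTP) threshold
of \$38,201 per quality-adjusted life year (QALY) — three times 2022
per-capita GDP — and reports the incremental cost-effectiveness ratio
(ICER), one-way and probabilistic sensitivity analyses, a price-threshold
analysis for cemiplimab, and hazard-ratio-based subgroup analyses.

## Survival model

All survival laws are hazard-scale Weibull,

$$S(t) = \exp(-\lambda t^{\gamma}), \qquad h(t) = \lambda\gamma t^{\gamma-1},$$

with $t$ in **months** (30.4375 days). The monthly scale is forced by the
fitted chemotherapy-arm parameters themselves: $(\lambda, \gamma) =
(0.030040, 1.213530)$ for OS implies a median of
$(\ln 2/\lambda)^{1/\gamma} \approx 13.3$ months, matching the trial's
13.0-month median only if $t$ is months; PFS $(0.061800, 1.388300)$
likewise gives $\approx 5.7$ vs the trial's 5.0. Under a shared shape a
hazard ratio $h$ multiplies $\lambda$ exactly, so the intervention arm is
derived as $\gamma_{CCT} = \gamma_{PCT}$, $\lambda_{CCT} = h \times
\lambda_{PCT}$ (`scale_by_hr()`), giving 0.021328 (OS) and 0.034608
(PFS).

### Curve reconstruction and fitting

When survival inputs come from a published figure rather than printed
parameters, `reconstruct_pseudo_ipd()` inverts the Kaplan-Meier
construction from digitized (time, survival) coordinates plus the
numbers-at-risk table: within each risk-table interval the number of
censorings is solved iteratively (censoring assumed uniform in the
interval) so that the implied step function tracks the digitized drops
while the implied at-risk counts hit the published numbers. For curves
sampled on a regular grid, risk intervals are treated as right-closed: a
drop shown exactly at a risk-table time is deducted before the at-risk
comparison, since it represents events that occurred just before that
time. Without this convention a curve digitized at the same spacing as
the risk table silently converts 5-7% of events into censorings.

Candidate distributions (exponential, Weibull, log-logistic, log-normal)
are fitted to the reconstructed records by censored maximum likelihood
(`flexsurv::flexsurvreg`; the Weibull in proportional-hazards form, which
is exactly the parameterization above). Selection minimizes AIC with ties
broken by BIC and then by the candidate order; both criteria are
recomputed from the achieved log-likelihood with $n$ = number of records.

## Cohort model

Three states — progression-free, progressed (PD), dead — on a 21-day
cycle (the dosing interval of every drug in both arms). The default
engine is a partitioned survival model: state membership is read directly
off the two curves, $pfs(t) = S_{PFS}(t)$, $dead(t) = 1 - S_{OS}(t)$,
$pd(t)$ the remainder. This is the unique structure fully determined by
the two published curves. A `state_transition` variant derives explicit
per-cycle flows (PFS exits split between PD and death in proportion to
the alive-state mix, PD-to-death calibrated so cumulative death tracks
$1 - S_{OS}$); its occupancy is identical by construction and it exists
so transition-level bookkeeping can be inspected.

**Horizon.** The trace stops when 99% of the cohort is dead, evaluated on
the slower-dying (cemiplimab) arm so both arms share one grid, capped at
120 cycles (about 6.9 years).

**Half-cycle correction.** Accrual uses the average of start- and
end-of-cycle occupancy by default. This is a numerical-integration
choice, not a clinical one: trapezoidal accrual makes the discretization
error second order in the cycle length, and the package's refinement
check (halving the cycle changes undiscounted life-years by well under
1%) holds only under it; pure end-of-cycle evaluation leaves a first-order
error of about 2% of the life-year total at a 21-day cycle. The flag
`half_cycle = FALSE` restores end-of-cycle accrual.

**Curve crossing.** If a sampled or subgroup-specific hazard-ratio pair
makes $S_{PFS}$ exceed $S_{OS}$ (possible early in time when the OS
hazard ratio is near or above 1 while the PFS one is below it),
`build_trace()` errors by default; the subgroup and probabilistic
analyses instead clamp PD occupancy at zero, the standard
partitioned-survival repair. Clamping is what makes the published
dominated-subgroup results (e.g. females, OS hazard ratio 2.11)
computable at all, and about 3% of Monte Carlo draws need it.

## Costs, utilities, discounting

Only direct medical costs (2022 USD) enter. Per cycle, progression-free
occupancy carries the drug bill and routine follow-up (\$92.69);
progressed occupancy carries best supportive care (\$365.51); each newly
dead cohort fraction carries a one-time end-of-life cost (\$2,665.11).
Drug dosing: pemetrexed 500 mg/m² and paclitaxel 200 mg/m² at body
surface area 1.72 m², cisplatin 75 mg/m², carboplatin by the Calvert
formula AUC 5 × (CrCl 70 + 25) mg, cemiplimab a flat 350 mg. Prices are
per 100 mg with no vial rounding. Both arms get four induction
chemotherapy cycles weighted by the trial's regimen mix; the
pemetrexed-backbone fraction continues pemetrexed maintenance while
progression-free; cemiplimab runs at most 36 cycles (108 weeks).
Cemiplimab has no Chinese list price, so it is priced at per-cycle parity
with pembrolizumab: \$2,662.41 × 200 mg / 350 mg = \$1,521.38 per 100 mg.

Grade ≥3 treatment-emergent adverse events with incidence above 5%
(anemia, neutropenia) enter once at model entry, incidence-weighted, as
management costs and one-cycle utility decrements. Health-state utilities
are 0.804 (progression-free) and 0.321 (progressed). Every cash flow and
QALY is discounted at 5%/year, $(1.05)^{-t/365.25}$, at its cycle's end
time; life-years are reported discounted and undiscounted.

Two conventions the source analysis leaves open are configurable:
end-of-life cost applies to all deaths (not only post-progression ones),
and pemetrexed maintenance has no cycle cap of its own.

## Uncertainty analysis

* **One-way:** each parameter to its trial 95% CI, or ±20% where no CI is
  published (including the four chemotherapy-arm Weibull parameters),
  others at base; entries sorted by ICER spread.
* **Probabilistic (PSA):** 1,000 Monte Carlo iterations. Distributions
  follow the parameter-type convention — gamma for costs and creatinine
  clearance, beta for probabilities and utilities, normal (truncated at
  zero) for hazard ratios and body surface area — moment-matched to the
  base value with SD = (high − low)/3.92, i.e. the printed range read as
  a 95% interval. Parameters are sampled independently (no correlation
  structure is published); each arm's four sampled regimen proportions
  are renormalized to sum to one. The Weibull survival parameters stay
  fixed in PSA (no distribution is assigned to them) and vary only in the
  one-way analysis. The acceptability at a WTP value is the fraction of
  iterations with positive net monetary benefit, WTP × ΔQALY − ΔCost > 0,
  all evaluated on a single sample set.
* **Price threshold:** the incremental cost is affine in the cemiplimab
  unit price, so the deterministic mode solves ICER(price) = WTP in
  closed form; the probabilistic mode rescales each iteration's sampled
  cemiplimab spend by a common factor and bisects until acceptability is
  within one percentage point of 50%. Both modes are reported because the
  source analysis phrases the threshold both ways; they agree within a
  few percent here.
* **Subgroups:** subgroup hazard ratios replace the whole-population
  ones; everything else stays at base values, including the
  chemotherapy-arm curves. Point estimates are used as printed even when
  their CIs cross 1.

## The synthetic-data generator

`simulate_trial()` draws event times from the specified Weibull laws by
inverse transform, with independent exponential dropout and
administrative censoring; `digitize()` computes the Kaplan-Meier curve,
samples it on a regular grid, rounds the coordinates, and tabulates the
true numbers at risk at the grid times. Defaults mirror the study: the
published chemotherapy-arm laws, 2:1 arm sizes 312/154, hazard ratios
0.71/0.56, 24 months of follow-up, a 0.1-month digitization grid (a
two-year axis read at roughly pixel resolution, as dense point extraction
produces) and 3-decimal coordinate rounding.

What it emulates is grid digitization with rounding noise; what it does
**not** emulate: correlated PFS/OS at the patient level (independent
marginals only), digitizer click jitter beyond rounding (a uniform-jitter
option exists for robustness tests), reading errors in the at-risk table,
or the visual artifacts of a real published figure. Passing the recovery
tests therefore shows the reconstruction-fitting chain is faithful to
grid-digitized curves, not that any real figure was digitized correctly.
Coarser grids bias reconstructed event times late by up to one grid step
(the drop between grid points is assigned to the later point), which
inflates the fitted shape and, through the strong negative correlation of
the two Weibull parameters, deflates the scale; at the default grid this
bias is well inside sampling noise.

## Problem sizes and numerical choices

Test and validation runs use: recovery over 20 seeded replicates of
n = 500 (median relative error of both Weibull parameters under 10%,
Weibull selected in at least 18/20), 1,000 PSA iterations, occupancy
conservation asserted at 10⁻⁹ each cycle, the deterministic price solve
verified to 10⁻⁶ relative, and curve-crossing tolerance 10⁻⁶ before
clamping or erroring. All randomness is seed-controlled; identical seeds
give bit-identical Monte Carlo samples.

## Known limitations

* The published base-case life-years (2.49/1.83 per arm) are not
  derivable from the published survival parameters: the Weibull means
  those parameters imply are 22.4 and 16.9 months (1.87/1.41 undiscounted
  life-years). The engine exposes structure, half-cycle and horizon
  switches so the gap can be explored, but no simple convention closes
  it; this package's totals are internally consistent with the stated
  laws instead. Cost-side results agree with the published ones much more
  closely than QALY-side ones, and ratio quantities inherit a systematic
  upward shift of roughly 10-15%.
* Subgroup ICERs whose OS hazard ratio is near or above 1 divide by a
  near-zero incremental QALY and are therefore hypersensitive to the
  accounting gap above; they should be read as "far above any plausible
  threshold" rather than as point estimates.
* No spline or cure-fraction extrapolation, no time-varying hazard
  ratios, no indirect costs, no vial wastage, and no correlation between
  sampled parameters.
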