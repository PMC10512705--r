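---
title: "Model structure, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tacelen)
```

This vignette documents how the model is built, which conventions were
chosen where the problem admitted more than one reasonable answer, and what
the synthetic-data machinery does and does not establish.

## 1. The cohort model

Four mutually exclusive states — progression-free on first-line therapy
(PFS), recurrence-free after down-staging hepatectomy (RFS), progressed
disease on best supportive care (PD), and death — with strictly forward
transitions and a 21-day cycle. Time is measured in months
(30.4375 days/month, 365.25 days/year, so one cycle is 0.69 months or
0.0575 years). The whole cohort starts in PFS.

Per cycle, the engine applies:

* **Progression** from PFS at the conditional probability
  `1 − S_PFS(t+Δ)/S_PFS(t)` of the arm's PFS law.
* **Background mortality** from PFS and RFS at the per-cycle equivalent of
  the 7.4‰ annual Chinese all-cause rate
  (`prob_convert(0.0074, 365.25, 21)` ≈ 4.27·10⁻⁴). The PFS rate carries a
  scenario multiplier (×2/×4). Extending background mortality to RFS is an
  assumption toggle (`natural_mortality_in_rfs`); without it, post-surgery
  patients would be immortal until recurrence.
* **Down-staging surgery**: a constant per-cycle PFS→RFS probability over
  the first six months (surgery after conversion happens early in
  practice), calibrated by bisection so cumulative RFS entries equal the
  published fraction (15.3% combination arm, 1.8% lenvatinib arm). The
  calibration makes the published fraction an exact model property; the
  bisection runs 60 halvings on only the in-window cycles.
* **Recurrence** RFS→PD at the per-cycle equivalent of 19% over five years.
* **PD mortality**: see Section 3 — the most consequential open choice.

The run stops when 99% of the cohort has died or at the 200-cycle
(~11.5-year) cap, whichever comes first; reaching the cap below 99% emits a
warning with the final death occupancy rather than failing.

## 2. Survival inputs

Lenvatinib-arm PFS and OS follow log-logistic laws
`S(t) = (1 + (λt)^γ)^(-1)` with the published scale/shape values; their
medians are `1/λ` (6.56 and 11.73 months), matching the trial's reported
6.4 and 11.5 months. The combination arm is obtained by the
proportional-hazards power mapping `S^HR` (PFS HR 0.43, OS HR 0.45). The
source analysis does not state whether the hazard ratio was applied on the
hazard scale or the combination curves were refit within the family; `S^HR`
is the declared convention here, standard when only a hazard ratio is
published. It reproduces the combination arm's reported medians well
(e.g. `median_survival(apply_hr(pfs, 0.43))` ≈ 10.7 vs 10.6 months
reported) but keeps the log-logistic's heavy tail raised to a power < 1,
which is *heavier* than any log-logistic refit would be — see Section 6.

The fitting stage (`fit_parametric`, `fit_families`, `select_best`)
delegates the censored maximum-likelihood estimation to
`flexsurv::flexsurvreg` over six candidate families (exponential, Weibull,
log-normal, log-logistic, Gompertz, generalized gamma) and re-expresses
estimates in the `(λ, γ)` parameterisation. Selection is by minimal AIC,
ties broken by minimal BIC, then by fewest parameters. Fits on data without
events signal non-identifiability; non-convergence signals a fit failure
naming the family.

## 3. PD mortality: the structural fork

The publication does not state how the PD→death probability was derived.
Two constructions are implemented (`pd_death_mode`):

* **`"os_conditional"` (default):** PD occupants die with the OS curve's
  conditional per-cycle probability `1 − S_OS(t+Δ)/S_OS(t)`. Patients still
  in PFS or RFS are exposed only to background mortality, so overall cohort
  survival exceeds `S_OS` — the common construction in published TreeAge
  oncology models.
* **`"calibrated"`:** the cycle's total death increment implied by `S_OS`
  is assigned to PD occupants after subtracting background-mortality
  deaths, floored at zero. This forces cohort survival to track the OS
  curve (verified in tests to within 0.03 absolute over the first three
  years) at the price of an unassignable death deficit while PD is still
  empty.

The default was chosen because the published life years (1.57 discounted
for lenvatinib) *exceed* the mean survival of the OS law itself
(≈ 1.19 undiscounted years over the horizon): the source model demonstrably
did not anchor cohort survival to the OS curve, and the conditional-OS
construction reproduces the published discounted life years of both arms to
within a few percent.

## 4. Economics

All costs are 2022 USD (6.73 RMB/USD). Per cycle while in PFS: lenvatinib
($1,054.88 at 12 mg/day, scaling linearly with dose), hospitalization
($384.00) and tests ($359.96); TACE ($1,929.00) adds in for the first three
cycles of the combination arm (mean of three sessions); RFS accrues
hospitalization and tests; PD accrues best supportive care ($363.00 times
the BSC coverage fraction) **plus tests and hospitalization** (toggles
`test_in_pd`, `hosp_in_pd`, both on by default). One-time costs:
hepatectomy ($9,058.24) on each RFS entry, end-of-life care ($2,176.00) on
each death entry, and an incidence-weighted adverse-event lump at cycle 0
(the five grade ≥3 events with published incidences; $10.90 in the
lenvatinib arm).

Keeping monitoring and inpatient care running during PD is a deliberate
deviation from the narrower "BSC only" reading: supportive care as
described (paracentesis-level complication management, nutritional support)
is inpatient care, and with these toggles on, the model reproduces the
published ICER within ~1.3% and the scenario-analysis ICER family within
~5%, where the narrower reading lands the whole family ~10% low. The cost
of this choice is a higher absolute incremental cost; Section 6 explains
why both cannot be matched at once.

Utilities: PFS/RFS 0.76, PD 0.68, dead 0. Life years weight the alive
occupancy by the cycle length; QALYs weight each state by its utility.
Costs and outcomes are discounted at 5%/year with per-cycle exponent
`t = cycle · 21/365.25`; occupancy is taken at cycle start, with no
half-cycle correction by default (matching the engine the source analysis
used; `half_cycle_correction` switches to the start/end average, which
moves totals by well under 1%). Incremental results follow the standard
rules: ICER only when ΔQALY > 0; dominance flags otherwise; NMB =
WTP·ΔQALY − ΔCost at $38,201/QALY.

## 5. Sensitivity machinery

The one-way analysis perturbs each parameter of the published table to its
range bounds (±20% where no range was published; discount rate 0–8%) and
ranks ICER excursions. The probabilistic analysis draws: beta for
probabilities, incidences and utilities, and gamma for costs, both by
method of moments with SD = (high − low)/(2·1.96), i.e. ranges read as 95%
intervals (the published table names the families but not the
hyper-parameters); log-normal for hazard ratios with μ = log(point) and
σ = (log hi − log lo)/(2·1.96); and, for the survival λ and γ — whose
"log-logistic" distribution label is not meaningful for the parameters
themselves — normal on the log scale truncated to the published range via
inverse-CDF truncation (so draws are reproducible, with no rejection
loops). λ and γ are drawn independently; no covariance is published.
Degenerate ranges collapse to the base value; infeasible beta moments fall
back to uniform with a warning. The acceptability curve is evaluated on a
$0–60,000 grid in $500 steps, and the 50% crossing is linearly
interpolated. A fixed seed makes the whole PSA bit-reproducible.

Subgroup runs swap in each subgroup's two hazard ratios and keep all other
parameters at overall-population values (no subgroup-specific costs exist);
PSA widths are reused unchanged where requested. Scenario runs override
exactly the stated keys: recurrence 15%/20%; fixed horizons of 52/87/122
cycles (3/5/7 years, disabling the mortality stopping rule); BSC coverage
0.8/0.5 applied to the BSC cost only (no survival effect, matching the
published cost-only deltas); lenvatinib dose 8/10 mg scaling the drug cost;
and PFS direct-death multipliers 2/4.

## 6. What matches, what cannot, and why

With the defaults above, the recomputed base case reproduces the published
ICER, discounted life years, PSA acceptability, 50%-crossing threshold, and
the horizon/dose/mortality scenario orderings closely (run
`scripts/acceptance.R` to regenerate all of them). Two families of
quantities resist any faithful reconstruction:

* **QALY-side values.** The published QALY/LY pairs imply a mean utility of
  0.64 (combination), 0.67 (lenvatinib) and 0.62 (incremental) — all below
  the smallest state utility, 0.68. No occupancy and no uniform discounting
  convention can produce that with the published utilities, so the
  recomputed QALYs sit ~8–11% above the printed ones whatever the
  structure.
* **Absolute costs vs incremental cost.** The published "99% of the cohort
  dead at ~11 years" is unreachable under `S^HR` with the published
  log-logistic tails (the combination arm retains ~20% alive at the cap),
  indicating the source model's post-progression person-time was shorter
  than any curve derivable from the published parameters. A shorter PD tail
  with monitoring costs in PD explains all three published cost figures at
  once; with the published tails, one can match either the incremental cost
  (narrow PD costing) or the ICER family (default), not both. The default
  prefers the ICER family.

In the one-way analysis, the widest bar here is the RFS utility rather than
the PFS utility reported by the source: the two share the same value,
source and range, and the reconstructed recurrence-free pool persists
longer than the source model's (same tail issue as above), which hands the
RFS row the larger lever.

## 7. The synthetic-data module

`simulate_ipd` draws event times from the configured law by inverse
transform and censors administratively at a cut-off (default 25 months,
n ≈ 170/arm emulating the trial's lenvatinib arm; optional uniform accrual
staggers follow-up). `km_estimate` wraps the product-limit estimator and
attaches numbers at risk every 3 months (typical trial reporting — the
source's landmark spacing is not published). `reconstruct_ipd` inverts a
digitized curve: within each risk-table interval it allocates, at every
curve coordinate, the integer number of events that best matches the
survival drop given the current at-risk count, then assigns the residual
at-risk deficit as censoring at the interval end; without a risk table it
assumes no censoring before the last coordinate and flags the output. Round
trips (simulate → estimate → reconstruct → estimate) reproduce survival
coordinates within 0.02 at trial-size n in the test suite.

What passing these tests shows: the fitting pipeline recovers known
generating laws (λ, γ within 5% at n = 5,000) and the reconstruction is
self-consistent. What they do not show: anything about digitization error,
informative censoring, or deviations of real HCC survival from the
log-logistic family — the generator emulates the *assumed* statistical
structure, not the trial.

## 8. Numerical choices and problem sizes

Hepatectomy calibration: 60 bisection halvings (resolution ~10⁻¹⁸ on the
probability). Median inversion: `uniroot` at 10⁻¹² tolerance with bracket
doubling. Transition rows are validated to sum to one within 10⁻¹²; traces
conserve occupancy within 10⁻⁹ per cycle. Degenerate inputs signal rather
than propagate: zero survival at a cycle start, probabilities above one,
increasing at-risk counts, empty report collections, all-censored fits.
Test problem sizes were chosen to keep Monte-Carlo error well inside the
asserted tolerances at interactive runtimes: 10⁵ draws for distribution
moments, 10⁴ patients for empirical-vs-law checks, 5·10³ for parameter
recovery, 10³ PSA replications (the published count), 200 patients for
round-trip checks.

## 9. Known limitations

* Cohort-level model: no patient-level heterogeneity, no tunnel states for
  TACE sessions, no time-varying hazard ratios.
* The PD tail discrepancy above means absolute per-arm costs carry a
  structural uncertainty of order 10% that no parameter setting removes.
* Utilities enter as constants; no adverse-event disutilities are published
  and none are applied.
* External validation of the extrapolated curves against other trials is
  out of scope.
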