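---
title: "Simulating coil-aware MRI scheduling: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating coil-aware MRI scheduling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilflow)
```

## The problem

An MRI examination needs a receiver coil matched to the body region —
head, torso, spine, knee and so on — mounted on the scanner before the
patient gets on the table. When consecutive examinations on the same
scanner need different coils, the technologist spends several extra
minutes per swap. Over a four-scanner department running a 16-hour day
(07:00–23:00) this sequence-dependent changeover time adds up to more
than an hour and a half of lost service time per day.

`coilflow` simulates such a department end to end and evaluates a
purely organisational intervention: reorder each scanner-day so that
examinations needing the same coil sit in contiguous (same or adjacent)
slots, then spend the freed minutes on additional daily examinations.
The experiment has two phases:

1. **Coil grouping.** Compare the as-booked (*baseline*) schedule
   against the grouped (*proposed*) schedule on identical request sets
   and quantify the drop in daily coil changes, preparation time and
   overtime.
2. **Capacity and income.** Add one, two or three examinations per day,
   with coils chosen so that their median durations fit inside the
   freed minutes, and report monthly totals, utilization, overtime,
   reimbursement points and income, at the national tariffs of 6,500
   budget points per examination without contrast and 11,500 with.

## Model structure

The simulation is a hybrid of a discrete-event patient flow and
agent-like resource state:

* **Patient path** — registration → dressing → (IV setup when a
  contrast injection is needed) → waiting → scan → (IV removal).
  Pre-scan stations delay when the patient is ready for the scanner;
  post-scan stations do not occupy the scanner.
* **Scanner state** — each of the four scanners (A–D) has a set of
  coils it can mount and carries its currently mounted coil from
  examination to examination, and overnight (`carry_over_coil = TRUE`;
  a nightly reset to a bare scanner is available but off by default —
  nothing suggests the department dismounts coils at close).
* **Service discipline** — each scanner serves its scanner-day slot
  sequence in order; an examination starts at the latest of the
  scanner's free time, the patient's ready time and the day's opening.
  Emergency patients carry a priority flag and lead their coil block in
  the grouped schedule.

Preparation time for an examination is decomposed as

$$\mathrm{prep} = b + c \cdot \mathbf{1}[\text{coil differs from mounted}],$$

with base setup $b$ and changeover surcharge $c$. Two observed
operating points (mean preparation 5.27 min at 40.38 changes/day and
4.04 min at 13.04 changes/day, both at 79 examinations/day) identify
both components as a 2×2 linear system
(`calibrate_prep_components()`), giving $b \approx 3.45$ min and
$c \approx 3.55$ min. The freed service time per day is then

$$\Delta = (\bar p_{\text{baseline}} - \bar p_{\text{proposed}}) \times
\text{exams/day},$$

which at the published operating points equals
`r sprintf("%.2f", saved_minutes_per_day(5.27, 4.04, 79))` minutes —
and, consistently, avoided changes × surcharge:
27.34 × 3.554 ≈ 97.2.

## The grouping policy

Within each scanner-day, `group_coil_sequence()` reorders examinations
so that equal coils form contiguous blocks:

* the block of the coil already mounted at day start opens the day when
  possible, so the first examination needs no changeover;
* remaining blocks follow in descending size, ties broken by the
  scanner's most-booked coil within the weekday band (Sun–Mon, Tue–Wed,
  Thu–Sat — `weekday_group()`), so the same coils gravitate to the same
  slots across the days of a band;
* within a block, emergency examinations lead and booked order is
  otherwise preserved;
* the day's **closing coil is pinned to the as-booked schedule's
  closing coil**.

The last rule deserves a note. A day with $d$ distinct coils needs at
least $d - 1$ internal changes, plus one entry change unless the
mounted coil is among the $d$; unconstrained grouping attains exactly
this bound (verified in the tests against exhaustive permutation
search up to length 8). But day $t$'s entry coil is day $t-1$'s exit
coil, so a grouping that freely chooses its exit coil can — rarely —
enter the next day worse-placed than the as-booked order would have,
breaking per-day dominance. Pinning each day's exit to the as-booked
exit makes both policies enter every day with the same mounted coil,
and then the grouped day can never need more changes than the booked
one: dominance holds on *every* scanner-day of *every* instance, not
just on average. The cost is at most one extra change on days whose
entry and exit coil coincide.

Regrouping redistributes the day's own multiset of appointment times
over the new slot order (patients keep their day and the day keeps its
morning/afternoon/evening session capacities); this is the minimal
adjustment consistent with moving same-coil examinations together, and
it keeps every scanner active in every session with demand.

## Synthetic demand: what it emulates, and what it does not

No examination log is shipped; `generate_requests()` synthesizes one
with the structure of a busy December:

| parameter | default | origin |
|---|---|---|
| bookings/day | 79 on average (2,449/31-day month) | department's monthly volume |
| patient mix | 74.34/5.93/19.74% out/emergency/inpatient | cohort counts 1819/145/483 (sum to exactly 1) |
| per-coil demand shares | Torso 51.5%, 8chHead 16.3%, TorsoHead 2.2%, Shoulder 1.7%, rest uniform | published per-coil exam counts; unattributed remainder spread uniformly |
| per-coil median duration | 25–99 min (cardiac longest) | published medians |
| booking-to-exam wait | exponential, per-coil mean 0.96–22 days | published means (only means are available) |
| contrast probability | 0.4 | not published; income projections never depend on it |
| scan dispersion | lognormal around the coil median, `sdlog = 0.25` | daily-mean variability of a few minutes |
| contrast factor | 1.15 | two scan segments, modestly longer in total |
| ancillary stations | reg 3, dressing 5, IV setup 5, IV removal 3 min; triangular ±50% | rule-of-thumb values; the source logs lack these stations |

Arrival counts are Poisson per service hour from a weekday × hour
calendar (uniform 79/16 per hour by default); a fixed-count mode books
exactly *n* per day for conservation experiments. Appointments are
drawn inside the service day, and the booking date is set back by the
per-coil wait, so appointment ≥ booking always holds.

Scanner routing: only two rows of the room map are public — the
cardiac coil runs only on scanner C, and the standard head coil splits
3%/97% across C and D. The remaining rows of
`default_compatibility()` are a reconstruction: usable-set sizes 8, 9,
10 and 7 for A–D, with probabilities filled by iterative proportional
fitting so the expected scanning minutes per day are even across
scanners — the emulated department ran all four rooms near 85%
utilization, so a load-balancing booking rule is the natural
completion. The full matrix is overridable in config.

Consequences for interpretation: demand-weighted mean scan time is
~36–40 min here versus the source department's daily mean of ~33 min,
and simulated baseline coil changes (~53/day) sit above the
department's ~40/day, because the reconstructed shares are more
concentrated than the real (unpublished) case mix. The package
therefore treats the *printed* KPI magnitudes as calibration inputs
where they are arithmetic (tariffs, freed-minutes identity) and as
*direction/structure* claims where they are simulation outputs:
dominance of the grouped policy, agreement of executed and scheduled
changeovers, recovery of generator shares — each tested directly.

## Phase-2 details

The minutes freed per day bound the added work:
`augment_schedule()` enumerates all multisets of size *k* from the
candidate coils (default: the four long-wait coils — flexible
torso-and-head, shoulder, 8-inch head, torso), keeps those whose
median durations sum within the budget, and takes the one using the
most of it. An infeasible *k* (e.g. one added examination inside 10
minutes when every median is ≥ 25) raises a `coilflow_infeasible`
error rather than silently truncating. Added examinations are placed
at the end of an existing block of their coil on the least-loaded
compatible scanner; income is reported as a without/with-contrast
bracket, so no contrast mix is assumed. Conversion to USD uses two
explicit parameters, 0.847 NTD per budget point and 30 NTD/USD,
which reproduce the published projection to the dollar.

The per-coil "waiting list clears earlier" comparison
(`wait_time_reduction()`) is reported qualitatively only: with a
single closed month and appointments fixed to their day, the last
completion time of a coil moves by hours, not days; week-scale
reductions require a cross-month backlog from which added slots pull
patients forward, which the generator deliberately does not model.

## Validation protocol

Each run is replicated (the study protocol: 8 replications, 95%
confidence intervals) with seeds `seed0, seed0 + 1, …`, and the two
policy arms share seeds so they see identical request sets — observed
differences are policy effects, not sampling noise. Indicator
distributions are compared with the two-sided Wilcoxon rank-sum test
at α = 0.05: exact enumeration when both samples have ≤ 10
observations and no ties, the tie-corrected normal approximation with
midranks otherwise (`rank_sum_test()`, backed by `stats::wilcox.test`;
the test suite checks the exact branch against a brute-force
enumeration over all rank partitions). Comparisons default to
day-level values (n = 31 per arm per replication), mirroring a
month-of-days validation table; per-replication comparison is
available.

## Numerical and testing choices

* All timestamps are POSIXct/UTC; generated times are rounded to whole
  seconds so CSV round-trips are exact.
* Determinism: equal `(calibration, days, seed)` triples give
  byte-identical logs; schedules and traces are reproducible under
  fixed seeds; replication *r* depends only on `seed0 + r − 1`.
* Overtime is clamped at zero per scanner-day (minutes past 23:00 of
  the last off-table time) and averaged across scanners; utilization
  is occupied minutes (preparation + scan) over the 16-hour day,
  capped at 100%.
* Percentages are rounded to two decimals and USD to whole dollars,
  matching how such projections are tabulated.
* Test problem sizes are chosen for depth per second: policy
  properties run on ~100 seeded 2–3-day instances plus exhaustive
  permutation oracles up to length 8 (8! orderings); distributional
  recovery uses 10,000 requests; full-month runs appear once per
  property that needs them. The whole suite completes in well under a
  minute.

## Known limitations

* The routing matrix beyond its two pinned rows, the per-coil demand
  shares beyond four published counts, and all ancillary station times
  are reconstructions; absolute KPI levels shift with them.
* No scanner maintenance windows, no staffing constraints (one
  technologist/nurse per active room is assumed non-binding), no
  age-dependent walking speeds.
* One closed month: no cross-month waiting-list backlog, hence
  qualitative-only wait-reduction reporting (above).
* The grouping heuristic is evaluated, not optimised — no integer
  programming or metaheuristic search over slot layouts.
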