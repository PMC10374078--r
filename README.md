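# coilflow

Discrete-event simulation of an MRI department with coil-aware
scheduling: how many minutes does a radiology service lose to swapping
receiver coils between consecutive examinations — and what happens to
capacity, overtime, waiting time and income when same-coil
examinations are grouped into adjacent slots instead?

The package is written for healthcare-operations researchers and
radiology service managers who want to evaluate a *purely
organisational* intervention (no extra staff, no extra scanners) in a
simulated four-scanner department before touching a real booking
system.

## The model in brief

Patients flow through registration → dressing → (IV setup) → waiting →
scan → (IV removal). Each of four scanners (A–D) can mount a subset of
11 coil types and keeps its mounted coil between examinations and
overnight. Preparation time for an examination decomposes as

```
prep = b + c · 1[required coil ≠ mounted coil]
```

with base setup `b` and changeover surcharge `c`. Two observed
operating points (mean prep 5.27 min at 40.38 changes/day vs 4.04 min
at 13.04 changes/day, at 79 exams/day) identify `b ≈ 3.45 min` and
`c ≈ 3.55 min` (`calibrate_prep_components()`). A scanner-day with `d`
distinct coils needs at least `d − 1` internal changeovers; the
grouping policy (`proposed_schedule()`) attains this lower bound —
verified against exhaustive permutation search — while never beating
the booked schedule's closing coil handover, which makes the grouped
policy provably no worse on *every* scanner-day. Freed service time is

```
Δ = (prep_baseline − prep_proposed) × exams/day        [min/day]
```

and is spent, in phase 2, on up to three extra examinations per day
whose median durations fit inside Δ, priced at the national tariffs of
6,500 budget points per examination without contrast and 11,500 with
(0.847 NTD/point, 30 NTD/USD).

## Worked example

```r
library(coilflow)
calib  <- default_calibration()
compat <- default_compatibility()

reqs <- generate_requests(calib, n_days = 31, seed = 2016)
nrow(reqs)
#> [1] 2456                      # ~79 booked examinations/day

sb <- baseline_schedule(reqs, compat, seed = 2016)   # as booked
sp <- proposed_schedule(reqs, compat, seed = 2016)   # coil-grouped
kb <- compute_kpis(run_simulation(sb, reqs, calib, seed = 2016), reqs, calib)
kp <- compute_kpis(run_simulation(sp, reqs, calib, seed = 2016), reqs, calib)

kb$summary$mean   # DailyMRIexamTime, MRIexamPrepTime, DailyOverTime, changes
#> [1]  39.55   5.85 147.95  53.26
kp$summary$mean
#> [1]  39.54   4.36 132.81  20.06
```

Grouping leaves the scan time itself untouched (39.5 min) but cuts
daily coil changes from 53.3 to 20.1, preparation from 5.85 to
4.36 min/exam, and end-of-day overtime from 148 to 133 min. The freed
minutes and their value:

```r
saved_minutes_per_day(5.85, 4.36, nrow(reqs) / 31)
#> [1] 117.97                    # minutes/day freed by fewer changeovers

points_and_income(3, 31, baseline_total = 2449)
#> $points_without 604500   $points_with 1069500
#> $usd_without     17067   $usd_with      30196
#> $pct_increase      3.8
```

Three added examinations per day over a 31-day month are a +3.8%
monthly volume increase worth 604,500–1,069,500 budget points, i.e.
US$17,067–US$30,196 depending on contrast use.

The full two-phase study is scripted:

```sh
Rscript analysis/01_generate_logs.R          # synthesize the month's log
Rscript analysis/02_phase1_coil_grouping.R   # grouped vs booked, 8 replications
Rscript analysis/03_phase2_capacity_income.R # +1..+3 patients/day, income
```

Each step prints its findings and writes tables under `results/`.

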