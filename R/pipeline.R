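# End-to-end orchestration of the two experimental phases.

#' Scenario configuration
#'
#' Aggregates everything one experimental arm needs: calibration,
#' routing matrix, the simulated month, replication protocol and
#' policy.
#'
#' @param calib Calibration ([default_calibration()]).
#' @param compat Routing matrix ([default_compatibility()]).
#' @param n_days Days in the simulated month (31 for December 2016).
#' @param start_date First service day.
#' @param policy `"baseline"` or `"proposed"`.
#' @param added_per_day Extra examinations per day (0--3); only valid
#'   with the proposed policy.
#' @param n_replications Replications per run (the study protocol used
#'   8).
#' @param seed0 First replication seed.
#' @param daily_total Fixed bookings per day, or `NULL` for Poisson
#'   counts from the hourly calendar.
#' @return List of class `mri_scenario_config`.
#' @export
scenario_config <- function(calib = default_calibration(),
                            compat = default_compatibility(),
                            n_days = 31,
                            start_date = as.Date("2016-12-01"),
                            policy = c("baseline", "proposed"),
                            added_per_day = 0,
                            n_replications = 8,
                            seed0 = 1,
                            daily_total = NULL) {
  policy <- match.arg(policy)
  stopifnot(added_per_day %in% 0:3)
  if (added_per_day > 0 && policy != "proposed")
    stop("added_per_day > 0 requires policy = 'proposed'")
  structure(list(calib = calib, compat = compat, n_days = n_days,
                 start_date = start_date, policy = policy,
                 added_per_day = added_per_day,
                 n_replications = n_replications, seed0 = seed0,
                 daily_total = daily_total),
            class = "mri_scenario_config")
}

#' Phase 1: coil-grouping experiment
#'
#' Replicates both policy arms on identical request sets (shared
#' seeds), compares the validation indicators with the rank-sum test,
#' tabulates per-scanner coil-change counts by weekday
#' (baseline -> proposed), and converts the preparation-time reduction
#' into freed minutes per day.
#'
#' @param config A [scenario_config()]; the `policy` field is ignored —
#'   phase 1 always runs both arms.
#' @return List of class `mri_phase1`: `baseline` and `proposed`
#'   replication summaries, `comparison` (per-day rank-sum table),
#'   `per_scanner_changes` (scanner x weekday, mean daily changes under
#'   each policy), `saved_minutes_per_day`, and `exams_per_day`.
#' @export
run_phase1 <- function(config) {
  if (!inherits(config, "mri_scenario_config"))
    stop("config must be built with scenario_config()")
  cb <- config; cb$policy <- "baseline"; cb$added_per_day <- 0
  cp <- config; cp$policy <- "proposed"; cp$added_per_day <- 0
  base <- replicate_runs(cb, config$n_replications, config$seed0)
  prop <- replicate_runs(cp, config$n_replications, config$seed0)
  comparison <- compare_scenarios(base, prop, mode = "per_day")

  weekday_changes <- function(summary) {
    all_ch <- dplyr::bind_rows(summary$changes)
    all_ch$weekday <- factor(weekday3(all_ch$day),
                             levels = c("Sun", "Mon", "Tue", "Wed", "Thu",
                                        "Fri", "Sat"))
    dplyr::summarise(dplyr::group_by(all_ch, scanner_id, weekday),
                     changes = mean(changes), .groups = "drop")
  }
  wb <- weekday_changes(base)
  wp <- weekday_changes(prop)
  per_scanner <- dplyr::rename(wb, baseline = changes)
  per_scanner$proposed <- wp$changes[match(
    paste(per_scanner$scanner_id, per_scanner$weekday),
    paste(wp$scanner_id, wp$weekday))]

  exams_per_day <- mean(base$total_exams) / config$n_days
  prep_b <- base$indicators$mean[base$indicators$indicator == "MRIexamPrepTime"]
  prep_p <- prop$indicators$mean[prop$indicators$indicator == "MRIexamPrepTime"]
  saved <- saved_minutes_per_day(prep_b, prep_p, exams_per_day)

  structure(list(baseline = base, proposed = prop, comparison = comparison,
                 per_scanner_changes = per_scanner,
                 saved_minutes_per_day = saved,
                 exams_per_day = exams_per_day),
            class = "mri_phase1")
}

#' Phase 2: capacity and income experiment
#'
#' For one, two and three added examinations per day inside the freed
#' minutes from phase 1: augments the grouped schedule, re-simulates,
#' and reports monthly totals, percentage increase, per-scanner
#' utilization, overtime (with a rank-sum check against the baseline
#' arm), reimbursement points and USD income, and the per-coil
#' reductions in the last-examination completion time at the largest
#' augmentation.
#'
#' @param config A [scenario_config()].
#' @param saved_minutes Freed minutes per day; when `NULL`, taken from
#'   `phase1`, which is computed if also `NULL`.
#' @param phase1 Optional [run_phase1()] result to reuse.
#' @param point_value_ntd,ntd_per_usd Tariff conversion parameters (see
#'   [points_and_income()]).
#' @return List of class `mri_phase2`: `capacity` tibble (one row per
#'   scenario: baseline, proposed, +1..+3 with totals, utilization,
#'   overtime, points, USD), `overtime_tests` (rank-sum p per k),
#'   `wait_reductions` (per added coil at k = 3), `saved_minutes`,
#'   `added_coils`.
#' @export
run_phase2 <- function(config, saved_minutes = NULL, phase1 = NULL,
                       point_value_ntd = 0.847, ntd_per_usd = 30) {
  if (is.null(saved_minutes)) {
    if (is.null(phase1)) phase1 <- run_phase1(config)
    saved_minutes <- phase1$saved_minutes_per_day
  }
  seed <- config$seed0
  requests <- generate_requests(config$calib, config$n_days, seed,
                                start_date = config$start_date,
                                daily_total = config$daily_total)
  sb <- baseline_schedule(requests, config$compat, seed)
  sp <- regroup_schedule(sb)
  tb <- run_simulation(sb, requests, config$calib, seed)
  tp <- run_simulation(sp, requests, config$calib, seed)
  kb <- compute_kpis(tb, requests, config$calib)
  kp <- compute_kpis(tp, requests, config$calib)
  baseline_total <- nrow(requests)

  row_of <- function(name, kpis, added, income) {
    util <- kpis$utilization_pct
    tibble::tibble(
      scenario = name,
      total_patients = baseline_total + added * config$n_days,
      pct_increase = if (added > 0)
        percent_increase(added * config$n_days, baseline_total) else NA_real_,
      util_A = util[["A"]], util_B = util[["B"]],
      util_C = util[["C"]], util_D = util[["D"]],
      overtime = kpis$summary$mean[kpis$summary$indicator == "DailyOverTime"],
      points_without = if (added > 0) income$points_without else NA_real_,
      points_with = if (added > 0) income$points_with else NA_real_,
      usd_without = if (added > 0) income$usd_without else NA_real_,
      usd_with = if (added > 0) income$usd_with else NA_real_)
  }
  rows <- list(row_of("baseline", kb, 0, NULL),
               row_of("proposed", kp, 0, NULL))
  tests <- list()
  traces_k <- list()
  for (k in 1:3) {
    sk <- augment_schedule(sp, k, saved_minutes, config$calib)
    tk <- run_simulation(sk, requests, config$calib, seed)
    kk <- compute_kpis(tk, dplyr::bind_rows(requests,
                                            attr(sk, "extra_requests")),
                       config$calib)
    income <- points_and_income(k, config$n_days, point_value_ntd,
                                ntd_per_usd, baseline_total = baseline_total)
    rows[[length(rows) + 1L]] <- row_of(paste0("+", k), kk, k, income)
    ts <- rank_sum_test(kb$daily$overtime, kk$daily$overtime)
    tests[[length(tests) + 1L]] <- tibble::tibble(
      added_per_day = k, statistic = ts$statistic, p_value = ts$p_value,
      significant = ts$p_value < 0.05)
    traces_k[[k]] <- tk
    if (k == 3) added_coils <- unique(attr(sk, "extra_requests")$coil)
  }
  waits <- lapply(added_coils, function(cl)
    tibble::tibble(coil = cl,
                   reduction_hours =
                     wait_time_reduction(tb, traces_k[[3]], cl)$total_hours))
  structure(list(capacity = dplyr::bind_rows(rows),
                 overtime_tests = dplyr::bind_rows(tests),
                 wait_reductions = dplyr::bind_rows(waits),
                 saved_minutes = saved_minutes,
                 added_coils = added_coils,
                 baseline_total = baseline_total),
            class = "mri_phase2")
}

#' Write a comparison table as CSV
#'
#' Layout mirrors the validation tables: indicator, group means +- SD,
#' p-value, significance stars.
#'
#' @param comparison Tibble from [compare_scenarios()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  df <- data.frame(
    indicator = comparison$indicator,
    group_a = sprintf("%.2f +- %.2f", comparison$mean_a, comparison$sd_a),
    group_b = sprintf("%.2f +- %.2f", comparison$mean_b, comparison$sd_b),
    p_value = signif(comparison$p_value, 4),
    stars = ifelse(comparison$p_value < 0.001, "***",
            ifelse(comparison$p_value < 0.01, "**",
            ifelse(comparison$p_value < 0.05, "*", ""))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
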