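# Validation indicators and KPIs computed from an event trace.

#' Mean-impute missing examination durations
#'
#' Records lacking on/off-table times receive the mean duration of the
#' complete records; complete records pass through unchanged.
#'
#' @param records Tibble/data frame with POSIXct columns `table_on`,
#'   `table_off` (either may be `NA`).
#' @return `records` with a numeric `exam_minutes` column, imputed
#'   where incomplete. Errors if no record is complete.
#' @export
impute_exam_time <- function(records) {
  mins <- as.numeric(difftime(records$table_off, records$table_on,
                              units = "mins"))
  if (all(is.na(mins)))
    stop("all records are missing on/off-table times; no mean to impute from")
  mins[is.na(mins)] <- mean(mins, na.rm = TRUE)
  records$exam_minutes <- mins
  records
}

#' Compute validation indicators and KPIs from an event trace
#'
#' Daily examination time (off-table minus on-table, averaged per day),
#' preparation time (on-table minus prep start), daily overtime (how
#' far each scanner's last off-table time runs past the 23:00 close,
#' clamped at zero and averaged across scanners), daily coil-change
#' counts, per-scanner utilization (occupied minutes over the 16-hour
#' day, capped at 100%), per-coil booking-to-examination waits, and
#' cohort totals.
#'
#' @param trace An `mri_trace` from [run_simulation()].
#' @param requests Request tibble (for booking times and patient mix);
#'   pass the same set used for the run.
#' @param calib Calibration (service-day window).
#' @return An object of class `mri_kpi_report`: list with `daily` (one
#'   row per day: `exam_time`, `prep_time`, `overtime`, `coil_changes`),
#'   `summary` (indicator, mean, sd), `utilization_pct` (named, per
#'   scanner), `wait_days` (per coil), `total_exams`,
#'   `patient_type_counts`.
#' @export
compute_kpis <- function(trace, requests, calib) {
  if (nrow(trace) == 0) {
    return(structure(list(
      daily = tibble::tibble(day = as.Date(character()),
                             exam_time = numeric(), prep_time = numeric(),
                             overtime = numeric(), coil_changes = numeric()),
      summary = tibble::tibble(indicator = character(), mean = numeric(),
                               sd = numeric()),
      utilization_pct = numeric(0),
      wait_days = tibble::tibble(coil = character(), wait_days = numeric()),
      total_exams = 0L,
      patient_type_counts = c(outpatient = 0L, emergency = 0L,
                              inpatient = 0L)),
      class = "mri_kpi_report"))
  }
  bad <- which(trace$table_off <= trace$table_on)
  if (length(bad) > 0)
    stop("table_off <= table_on at trace row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  tr <- tibble::as_tibble(trace)
  tr$exam_minutes <- as.numeric(difftime(tr$table_off, tr$table_on, "mins"))
  tr$prep_minutes <- as.numeric(difftime(tr$table_on, tr$prep_start, "mins"))
  scanners <- sort(unique(tr$scanner_id))
  days <- sort(unique(tr$day))
  close_of <- function(day) as.POSIXct(day, tz = "UTC") +
    calib$service_day$end_hour * 3600

  per_day <- lapply(days, function(d) {
    dd <- tr[tr$day == d, ]
    over <- vapply(scanners, function(s) {
      off <- dd$table_off[dd$scanner_id == s]
      if (length(off) == 0) return(0)
      max(0, as.numeric(difftime(max(off), close_of(d), units = "mins")))
    }, numeric(1))
    tibble::tibble(day = d,
                   exam_time = mean(dd$exam_minutes),
                   prep_time = mean(dd$prep_minutes),
                   overtime = mean(over),
                   coil_changes = sum(dd$coil_changed))
  })
  daily <- dplyr::bind_rows(per_day)

  util <- vapply(scanners, function(s) {
    occ <- vapply(days, function(d) {
      dd <- tr[tr$scanner_id == s & tr$day == d, ]
      min(sum(as.numeric(difftime(dd$table_off, dd$prep_start, units = "mins"))),
          16 * 60)
    }, numeric(1))
    mean(occ) / (16 * 60) * 100
  }, numeric(1))
  names(util) <- scanners

  ri <- match(tr$request_id, requests$request_id)
  waits <- tibble::tibble(
    coil = tr$coil,
    wait = as.numeric(difftime(tr$table_on, requests$booking_datetime[ri],
                               units = "days")))
  waits <- waits[!is.na(waits$wait), ]
  wait_days <- dplyr::summarise(dplyr::group_by(waits, coil),
                                wait_days = mean(wait), .groups = "drop")

  types <- requests$patient_type[ri]
  summary <- tibble::tibble(
    indicator = c("DailyMRIexamTime", "MRIexamPrepTime", "DailyOverTime",
                  "DailyCoilChangeOccurrence"),
    mean = c(mean(daily$exam_time), mean(daily$prep_time),
             mean(daily$overtime), mean(daily$coil_changes)),
    sd = c(stats::sd(daily$exam_time), stats::sd(daily$prep_time),
           stats::sd(daily$overtime), stats::sd(daily$coil_changes)))

  structure(list(daily = daily, summary = summary, utilization_pct = util,
                 wait_days = wait_days, total_exams = nrow(tr),
                 patient_type_counts = table(types)),
            class = "mri_kpi_report")
}

#' @export
print.mri_kpi_report <- function(x, ...) {
  cat("MRI KPI report:", x$total_exams, "examinations over",
      nrow(x$daily), "days\n")
  print(x$summary)
  cat("Utilization (%):",
      paste(names(x$utilization_pct),
            sprintf("%.2f", x$utilization_pct), collapse = "  "), "\n")
  invisible(x)
}

#' Write a KPI report as CSV and JSON
#'
#' @param report An `mri_kpi_report`.
#' @param csv_path,json_path Output paths (either may be `NULL` to
#'   skip).
#' @return The report, invisibly.
#' @export
write_kpi_report <- function(report, csv_path = NULL, json_path = NULL) {
  long <- dplyr::bind_rows(
    report$summary,
    tibble::tibble(indicator = paste0("DailyScanUtilRate_",
                                      names(report$utilization_pct)),
                   mean = as.numeric(report$utilization_pct), sd = NA_real_),
    tibble::tibble(indicator = "TotalExams",
                   mean = report$total_exams, sd = NA_real_))
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(long), csv_path, row.names = FALSE,
                     quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(
      summary = report$summary,
      utilization_pct = as.list(report$utilization_pct),
      wait_days = report$wait_days,
      total_exams = report$total_exams), json_path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Reduction in the last-examination completion time of one coil
#'
#' Compares when the final examination requiring `coil` finishes under
#' two runs; a positive value means the second run clears that coil's
#' waiting list earlier.
#'
#' @param baseline_trace,proposed_trace `mri_trace` objects covering the
#'   same request population per coil.
#' @param coil Coil type to compare; must appear in both traces.
#' @return List with `total_hours`, whole `days`, residual `hours`, and
#'   a formatted `text` ("D days H hours").
#' @export
wait_time_reduction <- function(baseline_trace, proposed_trace, coil) {
  for (nm in list(list(baseline_trace, "baseline"),
                  list(proposed_trace, "proposed"))) {
    if (!coil %in% nm[[1]]$coil)
      stop("coil ", coil, " absent from the ", nm[[2]], " trace")
  }
  delta <- as.numeric(difftime(
    max(baseline_trace$table_off[baseline_trace$coil == coil]),
    max(proposed_trace$table_off[proposed_trace$coil == coil]),
    units = "hours"))
  days <- trunc(delta / 24)
  hours <- round(delta - days * 24)
  list(total_hours = delta, days = days, hours = hours,
       text = sprintf("%d days %d hours", days, hours))
}
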