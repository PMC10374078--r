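# Discrete-event execution of a schedule: patients move through
# registration -> dressing -> (IV setup) -> waiting -> scan -> (IV
# removal); scanners serve their slot sequence with sequence-dependent
# coil-change preparation.

#' Split mean preparation time into setup and changeover components
#'
#' The observed mean preparation time per examination is a mixture:
#' `prep_mean = base + change_rate * coil_change_minutes`, where
#' `change_rate` is coil changes per examination. Two operating points
#' (e.g. the department before and after coil grouping) identify both
#' components as a 2x2 linear system.
#'
#' @param prep_mean_1,prep_mean_2 Mean preparation minutes at the two
#'   operating points.
#' @param change_rate_1,change_rate_2 Coil changes per examination at
#'   the two points (changes/day divided by exams/day).
#' @return List with `base_setup_minutes` and `coil_change_minutes`.
#'   Equal rates make the system singular and raise an error.
#' @export
#' @examples
#' calibrate_prep_components(5.27, 40.38 / 79, 4.04, 13.04 / 79)
calibrate_prep_components <- function(prep_mean_1, change_rate_1,
                                      prep_mean_2, change_rate_2) {
  if (isTRUE(all.equal(change_rate_1, change_rate_2)))
    stop("singular system: the two change rates are equal")
  change <- (prep_mean_1 - prep_mean_2) / (change_rate_1 - change_rate_2)
  base <- prep_mean_1 - change_rate_1 * change
  list(base_setup_minutes = base, coil_change_minutes = change)
}

#' Scanner preparation time for one examination
#'
#' Base technologist setup plus the coil-change surcharge when the
#' required coil differs from the mounted one (a bare scanner,
#' `mounted_coil = "none"`, always incurs the change).
#'
#' @param mounted_coil Currently mounted coil or `"none"`.
#' @param coil Required coil.
#' @param calib Calibration holding `base_setup_minutes` and
#'   `coil_change_minutes`.
#' @return Preparation minutes.
#' @export
prep_time <- function(mounted_coil, coil, calib) {
  calib$base_setup_minutes +
    if (!identical(mounted_coil, coil)) calib$coil_change_minutes else 0
}

#' Choose the examination room for a ready patient
#'
#' Returns the scheduled scanner when it can take the patient now
#' (compatible and idle at `now`); otherwise the compatible scanner that
#' frees up earliest. Never returns a scanner that cannot mount the
#' required coil.
#'
#' @param coil Required coil.
#' @param scheduled_scanner Scanner the booking assigned.
#' @param busy_until Named numeric/POSIXct vector: when each scanner is
#'   next free.
#' @param compat Routing/compatibility matrix.
#' @param now Current time (same scale as `busy_until`).
#' @return A scanner id.
#' @export
select_scanner <- function(coil, scheduled_scanner, busy_until, compat, now) {
  compatible <- colnames(compat)[compat[coil, ] > 0]
  if (length(compatible) == 0)
    stop("no scanner in the system can mount coil ", coil)
  if (scheduled_scanner %in% compatible &&
      busy_until[scheduled_scanner] <= now)
    return(scheduled_scanner)
  compatible[which.min(busy_until[compatible])]
}

#' Execute a schedule as a discrete-event simulation
#'
#' Each scanner serves its scanner-day slot sequence in order. A
#' patient's ready time is their (possibly regrouped) appointment plus
#' sampled registration, dressing and — for contrast examinations — IV
#' setup times. Scanner preparation starts at the later of the
#' scanner's free time, the patient's ready time and the day's opening;
#' it includes the coil-change surcharge iff the required coil differs
#' from the mounted one, which persists overnight unless
#' `calib$carry_over_coil` is `FALSE`. Scan durations are lognormal
#' around the coil's median; contrast examinations run two scan
#' segments totalling `contrast_scan_factor` times the draw.
#'
#' @param schedule An `mri_schedule`.
#' @param requests Request tibble covering every scheduled
#'   `request_id`; rows attached by [augment_schedule()] as
#'   `extra_requests` are included automatically.
#' @param calib Calibration (service-time parameters).
#' @param seed Integer seed; traces are reproducible under a fixed seed.
#' @param initial_mounted Coil mounted on every scanner before the first
#'   day (`"none"` for bare scanners).
#' @return An `mri_trace` tibble: `request_id`, `scanner_id`, `day`,
#'   `coil`, `prep_start`, `table_on`, `table_off`, `coil_changed`
#'   (POSIXct, UTC). Exactly one row per scheduled slot.
#' @export
run_simulation <- function(schedule, requests, calib, seed,
                           initial_mounted = "none") {
  extra <- attr(schedule, "extra_requests")
  if (!is.null(extra)) requests <- dplyr::bind_rows(requests, extra)
  missing_ids <- setdiff(schedule$request_id, requests$request_id)
  if (length(missing_ids) > 0)
    stop("schedule references unknown request_id(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  set.seed(seed)
  prof <- calib$coil_profiles
  sched <- tibble::as_tibble(schedule)
  sched <- sched[order(sched$scanner_id, sched$day, sched$slot_index), ]
  n <- nrow(sched)
  if (n == 0) {
    return(structure(tibble::tibble(
      request_id = character(), scanner_id = character(),
      day = as.Date(character()), coil = character(),
      prep_start = as.POSIXct(character(), tz = "UTC"),
      table_on = as.POSIXct(character(), tz = "UTC"),
      table_off = as.POSIXct(character(), tz = "UTC"),
      coil_changed = logical()), class = c("mri_trace", "tbl_df", "tbl",
                                           "data.frame")))
  }
  ri <- match(sched$request_id, requests$request_id)
  contrast <- requests$needs_contrast[ri]

  # pre-scan ancillary path (seconds)
  reg <- rtriangular(n, calib$registration_minutes) * 60
  dress <- rtriangular(n, calib$dressing_minutes) * 60
  ivs <- ifelse(contrast, rtriangular(n, calib$iv_setup_minutes) * 60, 0)
  ready <- as.numeric(sched$appointment_datetime) + reg + dress + ivs

  med <- stats::setNames(prof$median_exam_minutes, prof$coil)
  scan_min <- stats::rlnorm(n, log(med[sched$coil]), calib$exam_sdlog) *
    ifelse(contrast, calib$contrast_scan_factor, 1)

  day_open <- as.numeric(as.POSIXct(sched$day, tz = "UTC")) +
    calib$service_day$start_hour * 3600

  prep_start <- table_on <- table_off <- numeric(n)
  changed <- logical(n)
  for (s in unique(sched$scanner_id)) {
    idx <- which(sched$scanner_id == s)
    mounted <- initial_mounted
    free <- -Inf
    last_day <- NULL
    for (i in idx) {
      d <- sched$day[i]
      if (!identical(d, last_day)) {
        if (!isTRUE(calib$carry_over_coil)) mounted <- "none"
        last_day <- d
      }
      start <- max(free, ready[i], day_open[i])
      changed[i] <- !identical(mounted, sched$coil[i])
      prep <- prep_time(mounted, sched$coil[i], calib) * 60
      prep_start[i] <- start
      table_on[i] <- start + prep
      table_off[i] <- table_on[i] + scan_min[i] * 60
      free <- table_off[i]
      mounted <- sched$coil[i]
    }
  }
  structure(tibble::tibble(
    request_id = sched$request_id,
    scanner_id = sched$scanner_id,
    day = sched$day,
    coil = sched$coil,
    prep_start = as.POSIXct(prep_start, origin = "1970-01-01", tz = "UTC"),
    table_on = as.POSIXct(table_on, origin = "1970-01-01", tz = "UTC"),
    table_off = as.POSIXct(table_off, origin = "1970-01-01", tz = "UTC"),
    coil_changed = changed),
    class = c("mri_trace", "tbl_df", "tbl", "data.frame"))
}

#' Write an event trace to CSV
#'
#' Columns: `request_id`, `scanner_id`, `prep_start`, `table_on`,
#' `table_off`, `coil_changed` (ISO-8601 timestamps).
#'
#' @param trace An `mri_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace[, c("request_id", "scanner_id", "prep_start",
                                "table_on", "table_off", "coil_changed")])
  for (col in c("prep_start", "table_on", "table_off"))
    df[[col]] <- iso_format(df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
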