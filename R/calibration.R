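# Calibration tables: everything the generator and the simulator need to
# emulate one month of MRI department operations.

#' The eleven MRI receiver coil types
#'
#' Closed vocabulary of coil labels used throughout the package.
#'
#' @return Character vector of the 11 coil names.
#' @export
coil_types <- function() {
  c("StdHead", "Card.", "8chHead", "Nuro.", "Breast", "Torso",
    "Spine", "LowExtre", "TorsoHead", "Knee", "Shoulder")
}

#' Per-coil service profiles
#'
#' One row per coil type: the median on-table examination duration
#' (minutes), the mean appointment-to-examination wait (days), and the
#' coil's share of total demand. Durations and waits are the hospital's
#' December operating figures; demand shares are reconstructed from the
#' published per-coil exam counts where available, with the unattributed
#' remainder spread uniformly over the other coils.
#'
#' @return A tibble with columns `coil`, `median_exam_minutes`,
#'   `mean_wait_days`, `demand_share`. Shares sum to 1.
#' @export
default_coil_profiles <- function() {
  prof <- tibble::tibble(
    coil = coil_types(),
    median_exam_minutes = c(36, 99, 28, 30, 46, 36, 25, 25, 40, 27, 34),
    mean_wait_days      = c(0.96, 6, 7, 8, 9, 10, 13, 15, 21, 22, 22)
  )
  # Published exam counts: TorsoHead 53, Shoulder 41, 8chHead 398, Torso 1261
  # of 2447 total; remaining 694 exams spread uniformly over the other 7 coils.
  counts <- stats::setNames(rep((2447 - 53 - 41 - 398 - 1261) / 7, 11), prof$coil)
  counts[c("TorsoHead", "Shoulder", "8chHead", "Torso")] <- c(53, 41, 398, 1261)
  prof$demand_share <- as.numeric(counts[prof$coil] / 2447)
  prof$demand_share <- prof$demand_share / sum(prof$demand_share)
  prof
}

#' Default calibration for the synthetic-log generator and simulator
#'
#' Bundles every tunable the pipeline consumes: per-coil profiles,
#' patient-mix shares, the hourly demand calendar, service-time
#' parameters for each flow station, scan-duration dispersion, and the
#' service-day window (07:00--23:00, a 16-hour day).
#'
#' The preparation-time components (`base_setup_minutes`,
#' `coil_change_minutes`) are derived at build time by
#' [calibrate_prep_components()] from the two published operating points
#' (mean prep 5.27 min at 40.38 changes/day vs 4.04 min at 13.04
#' changes/day, at 79 exams/day).
#'
#' @param overrides Named list of fields to replace in the default set.
#' @return An object of class `mri_calibration` (a named list).
#' @export
#' @examples
#' calib <- default_calibration()
#' calib$patient_type_shares
default_calibration <- function(overrides = list()) {
  prep <- calibrate_prep_components(5.27, 40.38 / 79, 4.04, 13.04 / 79)
  calendar <- expand.grid(
    weekday = c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat"),
    hour = 0:23, stringsAsFactors = FALSE
  )
  calendar <- tibble::as_tibble(calendar[order(match(calendar$weekday,
    c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")), calendar$hour), ])
  calendar$rate <- ifelse(calendar$hour >= 7 & calendar$hour < 23, 79 / 16, 0)

  calib <- list(
    coil_profiles = default_coil_profiles(),
    # exact December cohort counts 1819/145/483 of 2447 (printed shares
    # 74.34/5.93/19.74% round from these and must sum to 1)
    patient_type_shares = c(outpatient = 1819, emergency = 145,
                            inpatient = 483) / 2447,
    exams_per_day = 79,
    arrivals_per_hour = calendar,
    service_day = list(start_hour = 7, end_hour = 23),
    contrast_probability = 0.4,
    contrast_scan_factor = 1.15,
    exam_sdlog = 0.25,
    base_setup_minutes = prep$base_setup_minutes,
    coil_change_minutes = prep$coil_change_minutes,
    # ancillary stations: rule-of-thumb means, triangular +/-50%
    registration_minutes = 3,
    dressing_minutes = 5,
    iv_setup_minutes = 5,
    iv_removal_minutes = 3,
    carry_over_coil = TRUE
  )
  calib[names(overrides)] <- overrides
  class(calib) <- "mri_calibration"
  validate_calibration(calib)
  calib
}

#' Validate a calibration object
#'
#' Checks the structural invariants: 11 coil profiles with positive
#' durations and non-negative waits, demand shares and patient-type
#' shares summing to 1, a 16-hour service day ending at 23:00, and a
#' demand calendar that is zero outside the service window.
#'
#' @param calib An `mri_calibration` object.
#' @return `calib`, invisibly; errors describe the violated invariant.
#' @export
validate_calibration <- function(calib) {
  prof <- calib$coil_profiles
  if (!setequal(prof$coil, coil_types()) || nrow(prof) != 11L)
    stop("coil_profiles must cover exactly the 11 known coil types")
  if (any(prof$median_exam_minutes <= 0))
    stop("median_exam_minutes must be positive")
  if (any(prof$mean_wait_days < 0))
    stop("mean_wait_days must be non-negative")
  if (abs(sum(prof$demand_share) - 1) > 1e-9)
    stop("coil demand_shares must sum to 1")
  if (abs(sum(calib$patient_type_shares) - 1) > 1e-9)
    stop("patient_type_shares must sum to 1")
  sd <- calib$service_day
  if (sd$end_hour != 23 || sd$end_hour - sd$start_hour != 16)
    stop("service day must span 16 hours and end at 23:00")
  cal <- calib$arrivals_per_hour
  outside <- cal$hour < sd$start_hour | cal$hour >= sd$end_hour
  if (any(cal$rate[outside] > 0))
    stop("arrivals_per_hour must be zero outside the service day")
  if (any(cal$rate < 0)) stop("arrivals_per_hour rates must be non-negative")
  invisible(calib)
}

#' Read a calibration config file
#'
#' Reads a YAML or JSON document whose top-level keys override fields of
#' the default calibration. `coil_profiles` may be given as a list of
#' records (coil, median_exam_minutes, mean_wait_days, demand_share).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `mri_calibration` object.
#' @export
read_calibration <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$coil_profiles))
    raw$coil_profiles <- tibble::as_tibble(raw$coil_profiles)
  if (!is.null(raw$patient_type_shares))
    raw$patient_type_shares <- unlist(raw$patient_type_shares)
  if (!is.null(raw$arrivals_per_hour))
    raw$arrivals_per_hour <- tibble::as_tibble(raw$arrivals_per_hour)
  if (!is.null(raw$service_day)) raw$service_day <- as.list(raw$service_day)
  default_calibration(overrides = raw)
}
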