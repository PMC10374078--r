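# Synthetic examination-request logs: generation and CSV round-trip.

request_columns <- c("request_id", "patient_type", "gender", "needs_contrast",
                     "priority", "coil", "booking_datetime",
                     "appointment_datetime")

#' Generate a synthetic month of MRI examination requests
#'
#' Draws booked examination requests with the statistical structure of a
#' real department month: per-day demand from the hourly arrival
#' calendar, patient type / gender / contrast flags from the calibrated
#' shares, coil type from the demand shares, and a booking date set back
#' from the appointment by an exponential per-coil wait with the
#' calibrated mean. Emergency patients carry the priority flag.
#'
#' @param calib An `mri_calibration` object (see [default_calibration()]).
#' @param n_days Number of service days to generate (>= 0).
#' @param seed Integer seed; equal `(calib, n_days, seed)` triples give
#'   identical output.
#' @param start_date First service day (a `Date`); defaults to
#'   2016-12-01, the simulated month.
#' @param daily_total If given, books exactly this many requests per day
#'   (hours drawn from the calendar weights) instead of Poisson counts
#'   per hour — used for conservation experiments at a fixed 79/day.
#' @return A tibble of requests, ordered by appointment time, with
#'   columns `request_id`, `patient_type`, `gender`, `needs_contrast`,
#'   `priority`, `coil`, `booking_datetime`, `appointment_datetime`
#'   (POSIXct, UTC).
#' @export
#' @examples
#' calib <- default_calibration()
#' reqs <- generate_requests(calib, n_days = 2, seed = 1)
#' nrow(reqs)
generate_requests <- function(calib, n_days, seed,
                              start_date = as.Date("2016-12-01"),
                              daily_total = NULL) {
  validate_calibration(calib)
  stopifnot(n_days >= 0)
  set.seed(seed)
  if (n_days == 0) {
    out <- tibble::tibble(
      request_id = character(), patient_type = character(),
      gender = character(), needs_contrast = logical(),
      priority = logical(), coil = character(),
      booking_datetime = as.POSIXct(character(), tz = "UTC"),
      appointment_datetime = as.POSIXct(character(), tz = "UTC"))
    return(out)
  }
  days <- start_date + seq_len(n_days) - 1L
  cal <- calib$arrivals_per_hour
  per_day <- lapply(days, function(day) {
    rates <- cal[cal$weekday == weekday3(day), ]
    rates <- rates[order(rates$hour), ]
    if (is.null(daily_total)) {
      counts <- stats::rpois(nrow(rates), rates$rate)
      hours <- rep(rates$hour, counts)
    } else {
      hours <- sort(sample(rates$hour, daily_total, replace = TRUE,
                           prob = rates$rate))
    }
    if (length(hours) == 0) return(NULL)
    appt <- as.POSIXct(day, tz = "UTC") + hours * 3600 +
      round(stats::runif(length(hours), 0, 3599))
    tibble::tibble(appointment_datetime = sort(appt))
  })
  out <- dplyr::bind_rows(per_day)
  n <- nrow(out)
  prof <- calib$coil_profiles
  out$request_id <- sprintf("R%06d", seq_len(n))
  out$patient_type <- sample(names(calib$patient_type_shares), n,
                             replace = TRUE, prob = calib$patient_type_shares)
  out$gender <- sample(c("female", "male"), n, replace = TRUE)
  out$needs_contrast <- stats::runif(n) < calib$contrast_probability
  out$priority <- out$patient_type == "emergency"
  out$coil <- sample(prof$coil, n, replace = TRUE, prob = prof$demand_share)
  wait_days <- stats::rexp(n, 1) * prof$mean_wait_days[match(out$coil, prof$coil)]
  out$booking_datetime <- out$appointment_datetime - round(wait_days * 86400)
  out[, request_columns]
}

#' Write examination requests to CSV
#'
#' Fixed column order (`request_id`, `patient_type`, `gender`,
#' `needs_contrast`, `priority`, `coil`, `booking_datetime`,
#' `appointment_datetime`), ISO-8601 timestamps, one header row.
#' `write_requests()` then [read_requests()] is the identity.
#'
#' @param requests A request tibble as from [generate_requests()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_requests <- function(requests, path) {
  df <- as.data.frame(requests[, request_columns])
  df$booking_datetime <- iso_format(df$booking_datetime)
  df$appointment_datetime <- iso_format(df$appointment_datetime)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read examination requests from CSV
#'
#' @param path CSV file written by [write_requests()] (or matching its
#'   column contract).
#' @return A request tibble; errors name any missing column, unknown
#'   coil label, or the row index of an unparseable timestamp.
#' @export
read_requests <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(request_columns, names(df))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) {
    return(generate_requests(default_calibration(), 0, 1))
  }
  bad_coil <- setdiff(unique(df$coil), coil_types())
  if (length(bad_coil) > 0)
    stop("unknown coil type(s): ", paste(bad_coil, collapse = ", "))
  out <- tibble::as_tibble(df[, request_columns])
  for (col in c("booking_datetime", "appointment_datetime")) {
    parsed <- iso_parse(out[[col]])
    if (anyNA(parsed))
      stop("unparseable timestamp in column ", col, " at row(s): ",
           paste(which(is.na(parsed)), collapse = ", "))
    out[[col]] <- parsed
  }
  out$needs_contrast <- out$needs_contrast == "TRUE"
  out$priority <- out$priority == "TRUE"
  out
}
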