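# Scheduling policies: as-booked baseline vs coil-grouped proposed, plus
# the phase-2 capacity augmentation.

SESSION_LEVELS <- c("morning", "afternoon", "evening")

session_of_hour <- function(hour) {
  ifelse(hour < 12, "morning", ifelse(hour < 17, "afternoon", "evening"))
}

new_schedule <- function(df, policy, compat) {
  df <- tibble::as_tibble(df)
  attr(df, "policy_name") <- policy
  attr(df, "compat") <- compat
  class(df) <- c("mri_schedule", class(df))
  df
}

#' Weekday group of the proposed policy
#'
#' The proposed policy plans coil usage over three weekday bands:
#' Sunday--Monday (G1), Tuesday--Wednesday (G2), Thursday--Saturday (G3).
#'
#' @param date A `Date` (or coercible) vector.
#' @return Character vector of `"G1"`, `"G2"` or `"G3"`.
#' @export
#' @examples
#' weekday_group(as.Date("2016-12-04"))  # a Sunday -> "G1"
weekday_group <- function(date) {
  wd <- as.POSIXlt(as.Date(date))$wday  # 0 = Sunday
  ifelse(wd <= 1, "G1", ifelse(wd <= 3, "G2", "G3"))
}

#' Count coil changeovers along an examination sequence
#'
#' A change is counted at every position whose required coil differs
#' from the coil mounted after the previous examination; the first
#' examination counts as a change iff it differs from
#' `initial_mounted_coil` (use `"none"` for a bare scanner — the first
#' mount then always counts).
#'
#' @param coils Character vector of coil types in execution order (may
#'   be empty).
#' @param initial_mounted_coil Coil mounted at sequence start, or
#'   `"none"`.
#' @return Non-negative integer count of changeovers.
#' @export
#' @examples
#' count_coil_changes(c("Torso", "Torso", "Spine"), "Torso")  # 1
count_coil_changes <- function(coils, initial_mounted_coil = "none") {
  n <- length(coils)
  if (n == 0) return(0L)
  prev <- c(initial_mounted_coil, coils[-n])
  sum(coils != prev)
}

#' Order a day's examinations into contiguous same-coil blocks
#'
#' Returns a permutation of `seq_along(coils)` in which equal coils are
#' contiguous. The block holding the currently mounted coil is placed
#' first when possible (so the day may start without a changeover);
#' remaining blocks follow in descending size with ties broken by a
#' canonical coil order. If `exit_coil` is given, that coil's block is
#' forced last, pinning the coil the scanner hands over to the next day.
#' Within a block, priority (emergency) examinations come first and the
#' original order is otherwise preserved.
#'
#' Without an exit constraint the ordering attains the minimum
#' changeover count achievable by any permutation: `d` distinct coils
#' cost `d - 1` internal changes, plus one entry change unless the
#' mounted coil is among them.
#'
#' @param coils Character vector of required coils, in booked order.
#' @param mounted Coil mounted at day start (`"none"` for bare).
#' @param exit_coil Optional coil whose block must close the day.
#' @param priority Optional logical vector; `TRUE` entries lead their
#'   block.
#' @param canonical Optional character vector giving the tie-break order
#'   of coils; defaults to [coil_types()].
#' @return Integer permutation of `seq_along(coils)`.
#' @export
group_coil_sequence <- function(coils, mounted = "none", exit_coil = NULL,
                                priority = NULL, canonical = coil_types()) {
  n <- length(coils)
  if (n == 0) return(integer(0))
  if (is.null(priority)) priority <- rep(FALSE, n)
  blocks <- unique(coils)
  size <- vapply(blocks, function(b) sum(coils == b), integer(1))
  rank <- match(blocks, canonical)
  rank[is.na(rank)] <- length(canonical) + match(blocks[is.na(rank)], blocks)
  # base order: descending size, canonical tie-break
  ord <- blocks[order(-size, rank)]
  if (!is.null(exit_coil)) {
    if (!exit_coil %in% blocks)
      stop("exit_coil ", exit_coil, " not present in the sequence")
    ord <- c(setdiff(ord, exit_coil), exit_coil)
  }
  lead <- if (mounted %in% blocks &&
              (is.null(exit_coil) || mounted != exit_coil ||
               length(blocks) == 1L)) mounted else NULL
  if (!is.null(lead)) ord <- c(lead, setdiff(ord, lead))
  idx <- unlist(lapply(ord, function(b) {
    i <- which(coils == b)
    i[order(!priority[i], i)]
  }), use.names = FALSE)
  as.integer(idx)
}

#' Baseline (as-booked) schedule
#'
#' Orders requests by appointment time and routes each to a scanner by
#' sampling the coil's routing probabilities, mirroring how the
#' department books rooms. Slots within a scanner-day follow appointment
#' order; sessions (morning/afternoon/evening) follow the appointment
#' hour.
#'
#' @param requests Request tibble from [generate_requests()].
#' @param compat Routing matrix from [default_compatibility()].
#' @param seed Integer seed for the routing draws.
#' @return An `mri_schedule` tibble with columns `scanner_id`, `day`,
#'   `session`, `slot_index`, `request_id`, `coil`, `priority`,
#'   `appointment_datetime`, `weekday_group`.
#' @export
baseline_schedule <- function(requests, compat, seed) {
  validate_compatibility(compat, sizes = NULL)
  df <- requests[order(requests$appointment_datetime), ]
  set.seed(seed)
  scanner <- character(nrow(df))
  scanners <- colnames(compat)
  for (cl in coil_types()) {
    i <- which(df$coil == cl)
    if (length(i) == 0) next
    scanner[i] <- sample(scanners, length(i), replace = TRUE,
                         prob = compat[cl, ])
  }
  df$scanner_id <- scanner
  hrs <- as.POSIXlt(df$appointment_datetime, tz = "UTC")
  df$day <- as.Date(df$appointment_datetime, tz = "UTC")
  df$session <- session_of_hour(hrs$hour)
  df$weekday_group <- weekday_group(df$day)
  df <- df[order(df$scanner_id, df$day, df$appointment_datetime), ]
  df$slot_index <- stats::ave(seq_len(nrow(df)),
                              df$scanner_id, as.integer(df$day),
                              FUN = seq_along)
  out <- df[, c("scanner_id", "day", "session", "slot_index", "request_id",
                "coil", "priority", "appointment_datetime", "weekday_group")]
  new_schedule(out, "baseline", compat)
}

#' Regroup a schedule into contiguous same-coil blocks
#'
#' Reorders each scanner-day of an existing schedule with
#' [group_coil_sequence()], carrying the mounted coil across days and
#' pinning each day's closing coil to the input schedule's closing coil
#' (so both policies hand the same coil to the next morning). The day's
#' multiset of appointment times is redistributed to the new slot order,
#' i.e. patients keep their day but receive adjusted times — the
#' "minimal adjustment" reading of the policy. The scheduled request
#' multiset, scanner assignments and per-day session capacities are all
#' preserved.
#'
#' @param schedule An `mri_schedule` (typically from
#'   [baseline_schedule()]).
#' @param initial_mounted Coil mounted on every scanner before day 1.
#' @return An `mri_schedule` with `policy_name` `"proposed"`.
#' @export
regroup_schedule <- function(schedule, initial_mounted = "none") {
  compat <- attr(schedule, "compat")
  parts <- list()
  for (s in sort(unique(schedule$scanner_id))) {
    sdf <- schedule[schedule$scanner_id == s, ]
    mounted <- initial_mounted
    for (d in as.list(sort(unique(sdf$day)))) {
      ddf <- sdf[sdf$day == d, ]
      ddf <- ddf[order(ddf$slot_index), ]
      # group demand ranking for tie-breaks: most-booked coil first
      # within this scanner's weekday group
      gdf <- sdf[sdf$weekday_group == ddf$weekday_group[1], ]
      canon <- names(sort(table(gdf$coil), decreasing = TRUE))
      ord <- group_coil_sequence(ddf$coil, mounted = mounted,
                                 exit_coil = ddf$coil[nrow(ddf)],
                                 priority = ddf$priority,
                                 canonical = canon)
      ddf <- ddf[ord, ]
      ddf$slot_index <- seq_len(nrow(ddf))
      appts <- sort(ddf$appointment_datetime)
      ddf$appointment_datetime <- appts
      ddf$session <- session_of_hour(as.POSIXlt(appts, tz = "UTC")$hour)
      mounted <- ddf$coil[nrow(ddf)]
      parts[[length(parts) + 1L]] <- ddf
    }
  }
  out <- dplyr::bind_rows(parts)
  new_schedule(out, "proposed", compat)
}

#' Proposed (coil-grouped) schedule
#'
#' Builds the baseline schedule under the same seed — so scanner routing
#' is identical and policy effects are paired — then regroups each
#' scanner-day into contiguous same-coil blocks with
#' [regroup_schedule()].
#'
#' @inheritParams baseline_schedule
#' @return An `mri_schedule` with `policy_name` `"proposed"`.
#' @export
proposed_schedule <- function(requests, compat, seed) {
  regroup_schedule(baseline_schedule(requests, compat, seed))
}

#' Per-scanner-day coil-change counts of a schedule
#'
#' Applies [count_coil_changes()] to each scanner-day's slot sequence,
#' carrying the mounted coil overnight.
#'
#' @param schedule An `mri_schedule`.
#' @param initial_mounted Coil mounted before day 1 (`"none"`).
#' @return Tibble with `scanner_id`, `day`, `changes`.
#' @export
schedule_coil_changes <- function(schedule, initial_mounted = "none") {
  parts <- list()
  for (s in sort(unique(schedule$scanner_id))) {
    sdf <- schedule[schedule$scanner_id == s, ]
    mounted <- initial_mounted
    for (d in as.list(sort(unique(sdf$day)))) {
      coils <- sdf$coil[sdf$day == d][order(sdf$slot_index[sdf$day == d])]
      parts[[length(parts) + 1L]] <- tibble::tibble(
        scanner_id = s, day = d,
        changes = count_coil_changes(coils, mounted))
      mounted <- coils[length(coils)]
    }
  }
  dplyr::bind_rows(parts)
}

#' Add extra daily examinations inside the freed minutes
#'
#' Phase-2 capacity experiment: appends `k_per_day` examinations per
#' scheduled day, with coils chosen from `candidate_coils` so that the
#' sum of their median durations fits within the minutes per day freed
#' by the grouping policy. Among feasible coil multisets the one using
#' the most of the freed time is taken (deterministic tie-break by coil
#' order). Each added examination is placed at the end of an existing
#' block of its coil on the least-loaded compatible scanner-day, or
#' appended as a new closing block when the coil is not scheduled that
#' day.
#'
#' @param schedule An `mri_schedule` (proposed policy).
#' @param k_per_day Number of added examinations per day (0--3).
#' @param saved_minutes_per_day Freed minutes available per day.
#' @param calib Calibration, for median durations and mean waits.
#' @param candidate_coils Coils eligible for the extra slots; defaults
#'   to the four long-wait coils used in the capacity experiment.
#' @return The augmented `mri_schedule`; the synthesized request rows
#'   ride along in `attr(, "extra_requests")`. `k_per_day = 0` returns
#'   the input unchanged. If no size-`k_per_day` multiset of candidate
#'   medians fits the budget, an error of class `coilflow_infeasible` is
#'   signalled (never silent truncation).
#' @export
augment_schedule <- function(schedule, k_per_day, saved_minutes_per_day,
                             calib,
                             candidate_coils = c("TorsoHead", "Shoulder",
                                                 "8chHead", "Torso")) {
  stopifnot(k_per_day %in% 0:3, saved_minutes_per_day >= 0)
  if (k_per_day == 0) return(schedule)
  prof <- calib$coil_profiles
  med <- stats::setNames(prof$median_exam_minutes, prof$coil)[candidate_coils]
  combos <- as.matrix(expand.grid(rep(list(seq_along(candidate_coils)),
                                      k_per_day)))
  combos <- combos[!apply(combos, 1, is.unsorted), , drop = FALSE]
  sums <- apply(combos, 1, function(i) sum(med[i]))
  ok <- sums <= saved_minutes_per_day
  if (!any(ok)) {
    stop(structure(class = c("coilflow_infeasible", "error", "condition"),
      list(message = sprintf(
        "no combination of %d examination(s) from {%s} fits within %.2f saved minutes",
        k_per_day, paste(candidate_coils, collapse = ", "),
        saved_minutes_per_day), call = sys.call())))
  }
  pick <- combos[which(ok)[which.max(sums[ok])], ]
  add_coils <- candidate_coils[pick]

  compat <- attr(schedule, "compat")
  policy <- attr(schedule, "policy_name")
  sched <- tibble::as_tibble(schedule)
  extra <- list()
  genders <- c("female", "male")
  for (d in as.list(sort(unique(sched$day)))) {
    for (i in seq_len(k_per_day)) {
      cl <- add_coils[i]
      compatible <- colnames(compat)[compat[cl, ] > 0]
      today <- sched[sched$day == d & sched$scanner_id %in% compatible, ]
      loads <- table(factor(today$scanner_id, levels = compatible))
      has_block <- vapply(compatible, function(s)
        any(today$coil[today$scanner_id == s] == cl), logical(1))
      cand <- if (any(has_block)) compatible[has_block] else compatible
      target <- cand[which.min(loads[cand])]
      tdf <- today[today$scanner_id == target, ]
      tdf <- tdf[order(tdf$slot_index), ]
      pos <- if (any(tdf$coil == cl)) max(which(tdf$coil == cl)) else nrow(tdf)
      appt <- if (pos >= 1 && nrow(tdf) > 0) tdf$appointment_datetime[max(pos, 1)]
              else as.POSIXct(d, tz = "UTC") + calib$service_day$start_hour * 3600
      rid <- sprintf("ADD-%s-%d", format(d), i)
      extra[[length(extra) + 1L]] <- tibble::tibble(
        request_id = rid, patient_type = "outpatient",
        gender = genders[(i %% 2) + 1L], needs_contrast = FALSE,
        priority = FALSE, coil = cl,
        booking_datetime = appt -
          round(prof$mean_wait_days[prof$coil == cl] * 86400),
        appointment_datetime = appt)
      newrow <- tibble::tibble(
        scanner_id = target, day = d,
        session = session_of_hour(as.POSIXlt(appt, tz = "UTC")$hour),
        slot_index = pos + 0.5, request_id = rid, coil = cl,
        priority = FALSE, appointment_datetime = appt,
        weekday_group = weekday_group(d))
      sched <- dplyr::bind_rows(sched, newrow)
      # renumber the affected scanner-day
      sel <- sched$scanner_id == target & sched$day == d
      o <- order(sched$slot_index[sel])
      sched$slot_index[sel][o] <- seq_len(sum(sel))
    }
  }
  sched <- sched[order(sched$scanner_id, sched$day, sched$slot_index), ]
  out <- new_schedule(sched, policy, compat)
  attr(out, "extra_requests") <- dplyr::bind_rows(extra)
  out
}

#' Write a schedule to CSV
#'
#' Columns: `scanner_id`, `day`, `session`, `slot_index`, `request_id`,
#' `coil`.
#'
#' @param schedule An `mri_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  df <- as.data.frame(schedule[, c("scanner_id", "day", "session",
                                   "slot_index", "request_id", "coil")])
  df$day <- format(df$day)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
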