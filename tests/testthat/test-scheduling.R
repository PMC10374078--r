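calib <- default_calibration()
compat <- default_compatibility()

one_request <- function(coil, when = "2016-12-05 10:00:00",
                        type = "outpatient") {
  tibble::tibble(
    request_id = paste0("R-", coil, "-", substr(when, 12, 13)),
    patient_type = type, gender = "female", needs_contrast = FALSE,
    priority = type == "emergency", coil = coil,
    booking_datetime = as.POSIXct(when, tz = "UTC") - 86400,
    appointment_datetime = as.POSIXct(when, tz = "UTC"))
}

requests_for <- function(coils, day = "2016-12-05") {
  df <- dplyr::bind_rows(lapply(seq_along(coils), function(i)
    one_request(coils[i], sprintf("%s %02d:%02d:00", day, 8 + i %/% 4,
                                  (i %% 4) * 15))))
  df$request_id <- sprintf("R%02d", seq_along(coils))
  df
}

test_that("weekday bands map Sun/Mon, Tue/Wed, Thu-Sat", {
  dec <- seq(as.Date("2016-12-01"), as.Date("2016-12-31"), by = 1)
  wd <- weekdays(dec, abbreviate = TRUE)
  grp <- weekday_group(dec)
  expect_true(all(grp[wd %in% c("Sun", "Mon")] == "G1"))
  expect_true(all(grp[wd %in% c("Tue", "Wed")] == "G2"))
  expect_true(all(grp[wd %in% c("Thu", "Fri", "Sat")] == "G3"))
})

test_that("coil-change counting follows the transition definition", {
  expect_equal(count_coil_changes(character(0), "Torso"), 0L)
  expect_equal(count_coil_changes(rep("Torso", 3), "Torso"), 0L)
  expect_equal(count_coil_changes(rep("Torso", 3), "none"), 1L)
  for (n in c(2, 5, 8)) {
    alt <- rep(c("Knee", "Spine"), length.out = n)
    expect_equal(count_coil_changes(alt, "Knee"), n - 1L)
  }
})

test_that("baseline routing honors the pinned probabilities", {
  sched <- baseline_schedule(one_request("Card."), compat, seed = 1)
  expect_equal(sched$scanner_id, "C")

  many <- dplyr::bind_rows(lapply(1:10000, function(i) {
    r <- one_request("StdHead"); r$request_id <- paste0("S", i); r
  }))
  sched <- baseline_schedule(many, compat, seed = 2)
  expect_lt(abs(mean(sched$scanner_id == "D") - 0.97), 0.01)

  empty <- one_request("Torso")[0, ]
  expect_equal(nrow(baseline_schedule(empty, compat, seed = 1)), 0)

  bad <- compat
  bad["Knee", ] <- 0
  expect_error(baseline_schedule(one_request("Knee"), bad, seed = 1),
               "all-zero")
})

test_that("grouping produces contiguous blocks with minimal changes", {
  reqs <- requests_for(c("Torso", "Spine", "Torso", "Spine"))
  sp <- proposed_schedule(reqs, compat, seed = 4)
  for (s in unique(sp$scanner_id)) {
    coils <- sp$coil[sp$scanner_id == s][order(sp$slot_index[sp$scanner_id == s])]
    expect_equal(count_coil_changes(coils[-1], coils[1]),
                 length(unique(coils)) - 1L)
  }

  # d distinct coils on one scanner-day -> exactly d - 1 internal changes
  set.seed(42)
  for (rep in 1:20) {
    coils <- sample(coil_types()[-c(1, 2)], sample(3:8, 1), replace = TRUE)
    ord <- group_coil_sequence(coils, mounted = "none")
    grouped <- coils[ord]
    expect_equal(count_coil_changes(grouped[-1], grouped[1]),
                 length(unique(coils)) - 1L)
    expect_equal(sort(ord), seq_along(coils))
  }
})

test_that("the proposed schedule is a compatible permutation of its input", {
  reqs <- generate_requests(calib, 7, seed = 9)
  sb <- baseline_schedule(reqs, compat, seed = 9)
  sp <- proposed_schedule(reqs, compat, seed = 9)
  expect_setequal(sp$request_id, reqs$request_id)
  expect_equal(nrow(sp), nrow(reqs))
  for (i in seq_len(nrow(sp)))
    expect_true(compat[sp$coil[i], sp$scanner_id[i]] > 0)
  # same routing as baseline (paired arms)
  m <- match(sb$request_id, sp$request_id)
  expect_equal(sp$scanner_id[m], sb$scanner_id)
  # per-day session capacities preserved
  tb <- table(sb$scanner_id, sb$day, sb$session)
  tp <- table(sp$scanner_id, sp$day, sp$session)
  expect_equal(tb, tp)
})

test_that("proposed never schedules more scanner-day changes than baseline", {
  for (seed in 1:25) {
    reqs <- generate_requests(calib, 3, seed = seed, daily_total = 25)
    sb <- baseline_schedule(reqs, compat, seed = seed)
    sp <- regroup_schedule(sb)
    cb <- schedule_coil_changes(sb)
    cp <- schedule_coil_changes(sp)
    key <- paste(cb$scanner_id, cb$day)
    expect_true(all(cp$changes[match(key, paste(cp$scanner_id, cp$day))] <=
                      cb$changes))
  }
})

test_that("emergency patients lead their coil block", {
  reqs <- requests_for(rep(c("Torso", "Spine"), 3))
  reqs$patient_type[4] <- "emergency"
  reqs$priority[4] <- TRUE
  sp <- proposed_schedule(reqs, compat, seed = 1)
  for (s in unique(sp$scanner_id)) {
    sdf <- sp[sp$scanner_id == s, ]
    sdf <- sdf[order(sdf$slot_index), ]
    for (cl in unique(sdf$coil)) {
      blk <- sdf[sdf$coil == cl, ]
      if (any(blk$priority))
        expect_true(all(which(blk$priority) <= sum(blk$priority)))
    }
  }
})

test_that("capacity augmentation fits the freed minutes or says why not", {
  reqs <- generate_requests(calib, 4, seed = 6, daily_total = 30)
  sp <- proposed_schedule(reqs, compat, seed = 6)

  expect_identical(augment_schedule(sp, 0, 97.17, calib), sp)

  aug <- augment_schedule(sp, 3, 97.17, calib)
  extra <- attr(aug, "extra_requests")
  expect_equal(nrow(extra), 3 * 4)
  expect_true(all(extra$coil %in% c("TorsoHead", "Shoulder", "8chHead",
                                    "Torso")))
  meds <- calib$coil_profiles$median_exam_minutes[
    match(extra$coil[1:3], calib$coil_profiles$coil)]
  expect_lte(sum(meds), 97.17)
  expect_equal(nrow(aug), nrow(sp) + 12)
  # added exams sit adjacent to a same-coil slot where one exists
  for (i in seq_len(nrow(aug))) {
    if (!grepl("^ADD-", aug$request_id[i])) next
    sdf <- aug[aug$scanner_id == aug$scanner_id[i] & aug$day == aug$day[i], ]
    sdf <- sdf[order(sdf$slot_index), ]
    pos <- which(sdf$request_id == aug$request_id[i])
    neighbors <- sdf$coil[c(pos - 1, pos + 1)]
    same_day_others <- sdf$coil[-pos]
    if (aug$coil[i] %in% same_day_others)
      expect_true(aug$coil[i] %in% stats::na.omit(neighbors))
  }

  expect_error(augment_schedule(sp, 1, 10, calib),
               class = "coilflow_infeasible")
})
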