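calib <- default_calibration()
compat <- default_compatibility()

test_that("preparation components solve the two operating points", {
  # oracle: the same 2x2 system solved numerically
  A <- rbind(c(1, 40.38 / 79), c(1, 13.04 / 79))
  oracle <- solve(A, c(5.27, 4.04))
  got <- calibrate_prep_components(5.27, 40.38 / 79, 4.04, 13.04 / 79)
  expect_equal(got$base_setup_minutes, oracle[1], tolerance = 1e-10)
  expect_equal(got$coil_change_minutes, oracle[2], tolerance = 1e-10)
  expect_equal(got$coil_change_minutes, 3.554, tolerance = 1e-3)
  expect_equal(got$base_setup_minutes, 3.453, tolerance = 1e-3)

  pinned <- calibrate_prep_components(5.0, 1.0, 3.0, 0.0)
  expect_equal(pinned$base_setup_minutes, 3.0)
  expect_equal(pinned$coil_change_minutes, 2.0)

  expect_error(calibrate_prep_components(5.27, 0.3, 5.27, 0.3), "singular")
})

test_that("prep time adds the changeover surcharge exactly when needed", {
  expect_equal(prep_time("Torso", "Torso", calib), calib$base_setup_minutes)
  expect_equal(prep_time("none", "Torso", calib),
               calib$base_setup_minutes + calib$coil_change_minutes)
  expect_equal(prep_time("Spine", "Torso", calib), 7.0, tolerance = 0.01)
})

test_that("room selection prefers the scheduled scanner, then earliest free", {
  busy <- c(A = 0, B = 0, C = 0, D = 0)
  expect_equal(select_scanner("Card.", "C", busy, compat, now = 0), "C")
  busy2 <- c(A = 3600, B = 900, C = 60, D = 0)
  expect_equal(select_scanner("Torso", "A", busy2, compat, now = 0), "D")
  expect_error(select_scanner("Knee", "A", busy,
                              compat[, c("C", "D"), drop = FALSE] * 0,
                              now = 0),
               "Knee")
})

test_that("traces conserve every scheduled slot without scanner overlap", {
  reqs <- generate_requests(calib, 5, seed = 21)
  for (policy in c("baseline", "proposed")) {
    sched <- if (policy == "baseline") baseline_schedule(reqs, compat, 21)
             else proposed_schedule(reqs, compat, 21)
    trace <- run_simulation(sched, reqs, calib, seed = 21)
    expect_equal(nrow(trace), nrow(sched))
    expect_setequal(trace$request_id, sched$request_id)
    expect_true(all(trace$table_off > trace$table_on))
    expect_true(all(trace$table_on >= trace$prep_start))
    for (s in unique(trace$scanner_id)) {
      tt <- trace[trace$scanner_id == s, ]
      tt <- tt[order(tt$prep_start), ]
      if (nrow(tt) > 1)
        expect_true(all(tt$prep_start[-1] >= tt$table_off[-nrow(tt)]))
    }
  }
})

test_that("traces are reproducible and empty schedules give empty traces", {
  reqs <- generate_requests(calib, 2, seed = 3)
  sched <- baseline_schedule(reqs, compat, 3)
  t1 <- run_simulation(sched, reqs, calib, seed = 5)
  t2 <- run_simulation(sched, reqs, calib, seed = 5)
  expect_identical(t1, t2)

  empty <- baseline_schedule(reqs[0, ], compat, 1)
  expect_equal(nrow(run_simulation(empty, reqs, calib, 1)), 0)
})

test_that("no changeover is flagged when the mounted coil already matches", {
  reqs <- dplyr::bind_rows(lapply(1:3, function(i) tibble::tibble(
    request_id = paste0("K", i), patient_type = "outpatient",
    gender = "male", needs_contrast = FALSE, priority = FALSE,
    coil = "Knee",
    booking_datetime = as.POSIXct("2016-12-04 08:00:00", tz = "UTC"),
    appointment_datetime = as.POSIXct("2016-12-05 08:00:00", tz = "UTC") +
      i * 1800)))
  sched <- baseline_schedule(reqs, compat, 1)
  sched$scanner_id <- "A"  # force a single room
  trace <- run_simulation(sched, reqs, calib, seed = 1,
                          initial_mounted = "Knee")
  expect_equal(trace$coil_changed, c(FALSE, FALSE, FALSE))
  trace2 <- run_simulation(sched, reqs, calib, seed = 1)
  expect_equal(trace2$coil_changed, c(TRUE, FALSE, FALSE))
})

test_that("executed changeover flags agree with the static counter", {
  reqs <- generate_requests(calib, 6, seed = 31)
  for (policy in c("baseline", "proposed")) {
    sched <- if (policy == "baseline") baseline_schedule(reqs, compat, 31)
             else proposed_schedule(reqs, compat, 31)
    trace <- run_simulation(sched, reqs, calib, seed = 31)
    for (s in unique(trace$scanner_id)) {
      mounted <- "none"
      tt <- trace[trace$scanner_id == s, ]
      for (d in sort(unique(tt$day))) {
        dd <- tt[tt$day == d, ]
        dd <- dd[order(dd$table_on), ]
        expect_equal(sum(dd$coil_changed),
                     count_coil_changes(dd$coil, mounted))
        mounted <- dd$coil[nrow(dd)]
      }
    }
  }
})

test_that("a schedule naming an unknown request fails loudly", {
  reqs <- generate_requests(calib, 1, seed = 2)
  sched <- baseline_schedule(reqs, compat, 2)
  sched$request_id[1] <- "GHOST"
  expect_error(run_simulation(sched, reqs, calib, 1), "GHOST")
})
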