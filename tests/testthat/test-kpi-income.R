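calib <- default_calibration()

test_that("missing exam durations are mean-imputed", {
  on <- as.POSIXct("2016-12-05 08:00:00", tz = "UTC") + c(0, 3600, 7200)
  rec <- tibble::tibble(table_on = on, table_off = on + c(30, 40, NA) * 60)
  rec$table_off[3] <- NA

  done <- impute_exam_time(rec)
  expect_equal(done$exam_minutes, c(30, 40, 35))
  expect_equal(done$table_on, rec$table_on)

  full <- tibble::tibble(table_on = on, table_off = on + 1800)
  expect_equal(impute_exam_time(full)$exam_minutes, rep(30, 3))

  none <- tibble::tibble(table_on = on, table_off = as.POSIXct(NA))
  expect_error(impute_exam_time(none), "no mean")
})

test_that("overtime and utilization follow their definitions", {
  reqs <- tibble::tibble(
    request_id = c("T001", "T002"), patient_type = "outpatient",
    gender = "female", needs_contrast = FALSE, priority = FALSE,
    coil = "Torso",
    booking_datetime = as.POSIXct("2016-12-01 08:00:00", tz = "UTC"),
    appointment_datetime = as.POSIXct("2016-12-05 08:00:00", tz = "UTC"))

  late <- make_trace("2016-12-05", c("A", "A"),
                     c("22:00:00", "23:00:00"),
                     c("22:05:00", "23:05:00"),
                     c("23:00:00", "23:40:00"))
  k <- compute_kpis(late, reqs, calib)
  expect_equal(k$daily$overtime, 40)

  early <- make_trace("2016-12-05", c("A", "A"),
                      c("08:00:00", "09:00:00"),
                      c("08:05:00", "09:05:00"),
                      c("08:50:00", "09:50:00"))
  expect_equal(compute_kpis(early, reqs, calib)$daily$overtime, 0)

  # 13.7 of 16 occupied hours -> 85.63%
  occ <- make_trace("2016-12-05", c("A", "A"),
                    c("07:00:00", "14:00:00"),
                    c("07:05:00", "14:05:00"),
                    c("13:42:00", "21:00:00"))
  util <- compute_kpis(occ, reqs, calib)$utilization_pct[["A"]]
  expect_equal(util, 13.7 / 16 * 100, tolerance = 1e-9)
  expect_equal(util, 85.63, tolerance = 0.01)

  bad <- make_trace("2016-12-05", "A", "08:00:00", "09:00:00", "08:30:00")
  expect_error(compute_kpis(bad, reqs, calib), "row")
})

test_that("tariff arithmetic reproduces the published projection table", {
  for (k in 1:3) {
    inc <- points_and_income(k, 31, baseline_total = 2449)
    expect_equal(inc$points_without, k * 31 * 6500)
    expect_equal(inc$points_with, k * 31 * 11500)
    expect_gte(inc$points_with, inc$points_without)
    expect_gte(inc$usd_with, 0)
  }
  inc3 <- points_and_income(3, 31)
  expect_equal(inc3$points_without, 604500)
  expect_equal(inc3$points_with, 1069500)
  expect_equal(inc3$usd_without, 17067)
  expect_equal(inc3$usd_with, 30196)

  zero <- points_and_income(0, 31)
  expect_equal(zero$points_without, 0)
  expect_equal(zero$usd_with, 0)

  # linearity in added examinations and month length
  i1 <- points_and_income(1, 31)
  i2 <- points_and_income(2, 62)
  expect_equal(i2$points_with, 4 * i1$points_with)
})

test_that("percentage increase matches to two decimals", {
  expect_equal(percent_increase(31, 2449), 1.27)
  expect_equal(percent_increase(62, 2449), 2.53)
  expect_equal(percent_increase(93, 2449), 3.80)
  expect_equal(percent_increase(0, 2449), 0.00)
  expect_error(percent_increase(10, 0), "positive")
})

test_that("freed minutes follow the mean-difference identity", {
  expect_equal(saved_minutes_per_day(5.27, 4.04, 2449 / 31), 97.17,
               tolerance = 1e-9)
  expect_equal(saved_minutes_per_day(5.0, 5.0, 100), 0)
  expect_equal(saved_minutes_per_day(4.0, 5.0, 10), -10)
})

test_that("wait-time reduction compares last completions per coil", {
  base <- make_trace("2016-12-30", c("A", "A"),
                     c("10:00:00", "12:00:00"),
                     c("10:05:00", "12:05:00"),
                     c("11:00:00", "13:00:00"),
                     coil = c("TorsoHead", "Knee"))
  expect_equal(wait_time_reduction(base, base, "Knee")$total_hours, 0)

  sooner <- base
  sooner$table_off <- sooner$table_off - (6 * 24 + 23) * 3600
  red <- wait_time_reduction(base, sooner, "TorsoHead")
  expect_equal(red$days, 6)
  expect_equal(red$hours, 23)
  expect_equal(red$text, "6 days 23 hours")

  expect_error(wait_time_reduction(base, sooner, "Breast"), "Breast")
})
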