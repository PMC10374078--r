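# Capacity and reimbursement arithmetic for the phase-2 experiment.
# Taiwan NHI global-budget tariffs: 6,500 points per MRI examination
# without contrast, 11,500 with contrast; points convert to currency at
# a floating point value.

POINTS_WITHOUT_CONTRAST <- 6500
POINTS_WITH_CONTRAST <- 11500

#' Monthly reimbursement projection for added daily examinations
#'
#' Brackets the added income between the all-without-contrast and
#' all-with-contrast tariffs, so the projection never depends on an
#' assumed contrast mix.
#'
#' @param added_per_day Added examinations per day (>= 0).
#' @param month_days Days in the month (>= 1).
#' @param point_value_ntd NTD value of one budget point (default 0.847).
#' @param ntd_per_usd NTD per USD (default 30).
#' @param baseline_total Optional baseline monthly examination count;
#'   when given, the percentage increase is included.
#' @return List of class `mri_income`: `added_per_day`, `month_days`,
#'   `points_without`, `points_with`, `usd_without`, `usd_with` (whole
#'   dollars), and `pct_increase` when `baseline_total` is given.
#' @export
#' @examples
#' points_and_income(3, 31)
points_and_income <- function(added_per_day, month_days,
                              point_value_ntd = 0.847, ntd_per_usd = 30,
                              baseline_total = NULL) {
  stopifnot(added_per_day >= 0, month_days >= 1)
  added <- added_per_day * month_days
  pw <- added * POINTS_WITHOUT_CONTRAST
  pc <- added * POINTS_WITH_CONTRAST
  out <- list(
    added_per_day = added_per_day,
    month_days = month_days,
    points_without = pw,
    points_with = pc,
    usd_without = round(pw * point_value_ntd / ntd_per_usd),
    usd_with = round(pc * point_value_ntd / ntd_per_usd))
  if (!is.null(baseline_total))
    out$pct_increase <- percent_increase(added, baseline_total)
  structure(out, class = "mri_income")
}

#' Percentage increase in monthly examinations
#'
#' @param added_total Added examinations over the month.
#' @param baseline_total Baseline monthly examination count (> 0).
#' @return Percentage, rounded to two decimals.
#' @export
#' @examples
#' percent_increase(93, 2449)  # 3.80
percent_increase <- function(added_total, baseline_total) {
  if (baseline_total <= 0) stop("baseline_total must be positive")
  round(100 * added_total / baseline_total, 2)
}

#' Daily minutes freed by a preparation-time reduction
#'
#' @param prep_mean_before,prep_mean_after Mean preparation minutes per
#'   examination under the two policies.
#' @param exams_per_day Examinations per day (> 0).
#' @return Minutes per day (negative when the policy is worse).
#' @export
#' @examples
#' saved_minutes_per_day(5.27, 4.04, 2449 / 31)  # 97.17
saved_minutes_per_day <- function(prep_mean_before, prep_mean_after,
                                  exams_per_day) {
  stopifnot(exams_per_day > 0)
  (prep_mean_before - prep_mean_after) * exams_per_day
}
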