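# Replication protocol and rank-sum comparison of indicator
# distributions.

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when both samples have at most 10 observations and
#' the pooled data are tie-free; otherwise the normal approximation
#' with midranks and the tie-corrected variance.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List with `statistic` (Mann-Whitney U for `sample_a`) and
#'   `p_value`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))$p_value  # 1/3 by exact enumeration
rank_sum_test <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- length(sample_a) <= 10 && length(sample_b) <= 10 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = exact, correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

run_one_scenario <- function(config, seed) {
  requests <- generate_requests(config$calib, config$n_days, seed,
                                start_date = config$start_date,
                                daily_total = config$daily_total)
  schedule <- if (identical(config$policy, "proposed")) {
    proposed_schedule(requests, config$compat, seed)
  } else {
    baseline_schedule(requests, config$compat, seed)
  }
  trace <- run_simulation(schedule, requests, config$calib, seed)
  kpis <- compute_kpis(trace, requests, config$calib)
  changes <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(trace), scanner_id, day),
    changes = sum(coil_changed), .groups = "drop")
  list(requests = requests, schedule = schedule, trace = trace,
       kpis = kpis, changes = changes)
}

#' Replicate a scenario and summarize its indicators
#'
#' Runs the full pipeline (generate requests, schedule under the
#' configured policy, simulate, compute KPIs) `n_replications` times
#' with seeds `seed0, seed0 + 1, ...`; replication `r` depends only on
#' `seed0 + r - 1`, so arms replicated from the same `seed0` are paired
#' on identical request sets.
#'
#' @param config A [scenario_config()].
#' @param n_replications Number of replications (>= 1).
#' @param seed0 First seed.
#' @return Object of class `mri_replication_summary`: `indicators`
#'   tibble (indicator, mean, sd, `ci_half_width` at 95%,
#'   n_replications; sd and CI are `NA` for a single replication),
#'   `values` (per-indicator per-replication means), `daily`
#'   (per-indicator day-level values pooled over replications), and the
#'   per-replication scanner-day change counts.
#' @export
replicate_runs <- function(config, n_replications, seed0) {
  stopifnot(n_replications >= 1)
  reps <- vector("list", n_replications)
  for (r in seq_len(n_replications)) {
    seed <- seed0 + r - 1L
    reps[[r]] <- tryCatch(run_one_scenario(config, seed),
      error = function(e) stop("replication with seed ", seed,
                               " failed: ", conditionMessage(e)))
  }
  inds <- c("DailyMRIexamTime", "MRIexamPrepTime", "DailyOverTime",
            "DailyCoilChangeOccurrence")
  values <- lapply(inds, function(ind) vapply(reps, function(rr)
    rr$kpis$summary$mean[rr$kpis$summary$indicator == ind], numeric(1)))
  names(values) <- inds
  daily_cols <- c(DailyMRIexamTime = "exam_time", MRIexamPrepTime = "prep_time",
                  DailyOverTime = "overtime",
                  DailyCoilChangeOccurrence = "coil_changes")
  daily <- lapply(daily_cols, function(col)
    unlist(lapply(reps, function(rr) rr$kpis$daily[[col]])))
  util <- do.call(rbind, lapply(reps, function(rr) rr$kpis$utilization_pct))
  totals <- vapply(reps, function(rr) rr$kpis$total_exams, numeric(1))
  n <- n_replications
  summ <- function(v) {
    s <- if (n >= 2) stats::sd(v) else NA_real_
    ci <- if (n >= 2) stats::qt(0.975, n - 1) * s / sqrt(n) else NA_real_
    c(mean(v), s, ci)
  }
  stats_m <- unname(t(vapply(values, summ, numeric(3))))
  indicators <- tibble::tibble(
    indicator = inds, mean = stats_m[, 1], sd = stats_m[, 2],
    ci_half_width = stats_m[, 3], n_replications = n)
  structure(list(config = config, seed0 = seed0, n_replications = n,
                 indicators = indicators, values = values, daily = daily,
                 utilization = util, total_exams = totals,
                 changes = lapply(reps, `[[`, "changes"),
                 kpis = lapply(reps, `[[`, "kpis")),
            class = "mri_replication_summary")
}

#' Compare two replicated scenarios indicator by indicator
#'
#' One row per indicator with group means, SDs and a two-sided rank-sum
#' test at alpha = 0.05. The default `per_day` mode compares day-level
#' indicator values pooled over replications (mirroring a month-of-days
#' comparison); `per_replication` compares replication means.
#'
#' @param summary_a,summary_b `mri_replication_summary` objects sharing
#'   the same indicator set.
#' @param mode `"per_day"` or `"per_replication"`.
#' @return Tibble: `indicator`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `statistic`, `p_value`, `significant` (p < 0.05).
#' @export
compare_scenarios <- function(summary_a, summary_b,
                              mode = c("per_day", "per_replication")) {
  mode <- match.arg(mode)
  ia <- summary_a$indicators$indicator
  ib <- summary_b$indicators$indicator
  if (!setequal(ia, ib))
    stop("indicator sets differ: ",
         paste(union(setdiff(ia, ib), setdiff(ib, ia)), collapse = ", "))
  rows <- lapply(ia, function(ind) {
    va <- if (mode == "per_day") summary_a$daily[[ind]] else summary_a$values[[ind]]
    vb <- if (mode == "per_day") summary_b$daily[[ind]] else summary_b$values[[ind]]
    ts <- rank_sum_test(va, vb)
    tibble::tibble(indicator = ind,
                   mean_a = mean(va), sd_a = stats::sd(va),
                   mean_b = mean(vb), sd_b = stats::sd(vb),
                   statistic = ts$statistic, p_value = ts$p_value,
                   significant = ts$p_value < 0.05)
  })
  dplyr::bind_rows(rows)
}
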