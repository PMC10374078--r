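# Independent oracles and small fixtures shared across tests.

# Brute-force two-sided Mann-Whitney p-value by enumerating every
# assignment of pooled ranks to group A (no ties assumed).
brute_force_ranksum_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(na + nb, na)
  w_all <- apply(combos, 2, function(i) sum(rank(pooled)[i]))
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# All permutations of 1..n as an n! x n matrix (n <= 8).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1), 1] <- k
    out[row:(row + nrow(sub) - 1), -1] <- matrix(rest[sub], nrow(sub))
    row <- row + nrow(sub)
  }
  out
}

# Exhaustive minimum coil-change count over every execution order.
min_changes_exhaustive <- function(coils, mounted = "none") {
  n <- length(coils)
  if (n == 0) return(0L)
  perms <- all_permutations(n)
  seqs <- matrix(coils[perms], nrow(perms))
  prev <- cbind(mounted, seqs[, -n, drop = FALSE])
  min(rowSums(seqs != prev))
}

# A small scenario for pipeline tests: one week, modest daily demand.
small_config <- function(seed0 = 1, n_replications = 2) {
  scenario_config(n_days = 7, n_replications = n_replications,
                  seed0 = seed0, daily_total = 20)
}

# Minimal handmade trace builder for KPI unit tests.
make_trace <- function(day, scanner, prep_start_hm, on_hm, off_hm,
                       coil = "Torso", changed = FALSE) {
  at <- function(hm) as.POSIXct(paste(day, hm), tz = "UTC")
  structure(tibble::tibble(
    request_id = sprintf("T%03d", seq_along(scanner)),
    scanner_id = scanner, day = as.Date(day), coil = coil,
    prep_start = at(prep_start_hm), table_on = at(on_hm),
    table_off = at(off_hm), coil_changed = changed),
    class = c("mri_trace", "tbl_df", "tbl", "data.frame"))
}
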