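# Scanner/coil compatibility and routing probabilities.

#' Default scanner-coil compatibility and routing matrix
#'
#' Four scanners (A--D) with usable-coil sets of sizes 8, 9, 10 and 7.
#' Two routing rows are pinned by the department's operating rules: the
#' cardiac coil runs only on scanner C (probability 1) and the standard
#' head coil splits 3%/97% across C and D. The remaining usable sets
#' are a reconstruction consistent with the set sizes (the full room
#' map is site-specific and config-overridable). The free rows are
#' filled by iterative proportional fitting so that the expected
#' scanning minutes per day are even across the four scanners — the
#' department the defaults emulate ran all four rooms at a similar
#' ~85% daily utilization, so a load-balancing booking rule is the
#' natural reconstruction.
#'
#' @param profiles Coil profiles used to weight the balancing (shares
#'   and median durations); defaults to [default_coil_profiles()].
#' @return An object of class `mri_compat`: an 11 x 4 matrix of routing
#'   probabilities (rows = coils, columns = scanners A--D); each row
#'   sums to 1 and is zero on scanners that cannot mount the coil.
#' @export
default_compatibility <- function(profiles = default_coil_profiles()) {
  scanners <- c("A", "B", "C", "D")
  usable <- list(
    A = setdiff(coil_types(), c("StdHead", "Card.", "Breast")),
    B = setdiff(coil_types(), c("StdHead", "Card.")),
    C = setdiff(coil_types(), "Shoulder"),
    D = c("StdHead", "8chHead", "Nuro.", "Torso", "Spine", "LowExtre",
          "TorsoHead")
  )
  m <- matrix(0, nrow = 11, ncol = 4,
              dimnames = list(coil_types(), scanners))
  for (s in scanners) m[usable[[s]], s] <- 1
  m["Card.", ] <- c(0, 0, 1, 0)
  m["StdHead", ] <- c(0, 0, 0.03, 0.97)
  free <- setdiff(coil_types(), c("Card.", "StdHead"))

  # expected scanning minutes per day carried by each coil
  w <- stats::setNames(profiles$demand_share * profiles$median_exam_minutes,
                       profiles$coil)
  pinned_load <- colSums(m[c("Card.", "StdHead"), ] *
                           w[c("Card.", "StdHead")])
  target <- pmax(sum(w) / 4 - pinned_load, 1e-6)
  p <- m[free, , drop = FALSE]
  p <- p / rowSums(p)
  for (iter in 1:100) {
    load <- colSums(p * w[free])
    p <- sweep(p, 2, target / pmax(load, 1e-12), `*`)
    p <- p / rowSums(p)
  }
  m[free, ] <- p
  structure(m, class = c("mri_compat", class(m)))
}

#' Validate a compatibility/routing matrix
#'
#' @param compat An 11 x 4 routing matrix (rows coils, columns scanners).
#' @param sizes Expected usable-set sizes per scanner, or `NULL` to skip
#'   the size check.
#' @return `compat`, invisibly.
#' @export
validate_compatibility <- function(compat, sizes = c(A = 8, B = 9, C = 10, D = 7)) {
  if (!all(coil_types() %in% rownames(compat)))
    stop("compatibility matrix must have one row per coil type")
  if (any(compat < 0)) stop("routing probabilities must be non-negative")
  rs <- rowSums(compat)
  zero <- rownames(compat)[rs == 0]
  if (length(zero) > 0)
    stop("coil(s) with all-zero routing row: ", paste(zero, collapse = ", "))
  if (any(abs(rs - 1) > 1e-9))
    stop("routing probabilities must sum to 1 per coil")
  if (!is.null(sizes)) {
    got <- colSums(compat > 0)
    if (!all(got[names(sizes)] == sizes))
      stop("usable-set sizes must be ",
           paste(names(sizes), sizes, sep = "=", collapse = ", "),
           "; got ", paste(names(got), got, sep = "=", collapse = ", "))
  }
  invisible(compat)
}

#' Usable coil set of one scanner
#'
#' @param compat Routing matrix from [default_compatibility()].
#' @param scanner_id Scanner label ("A".."D").
#' @return Character vector of coil types the scanner can mount.
#' @export
usable_coils <- function(compat, scanner_id) {
  rownames(compat)[compat[, scanner_id] > 0]
}
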