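#' Predicted m/z of a protonated oligomer ion
#'
#' `m/z = (n * M + z * m_p) / z` for an oligomer of `n` monomers of average
#' mass `M` carrying `z` protons. With `protonated = FALSE` the bare-mass
#' convention `n * M / z` is used instead; at ~17 kDa the two differ by only
#' ~60 ppm, well inside typical linear-mode tolerances, but the convention
#' is explicit and configurable. Average (not monoisotopic) masses are
#' assumed throughout — linear-mode MALDI at 17-120 kDa cannot resolve
#' isotopes.
#'
#' @param monomer_mass monomer average mass M in Da (> 0).
#' @param n stoichiometry (integer >= 1, vectorized).
#' @param z charge (integer >= 1, vectorized).
#' @param proton_mass proton mass in Da (default 1.00728).
#' @param protonated include the proton adducts? (default TRUE)
#' @return numeric m/z values (Th).
#' @examples
#' predict_mz(17413.8, n = 2, z = 1)  # ~34828.6
#' predict_mz(17413.8, n = 6, z = 2) == predict_mz(17413.8, n = 3, z = 1)
#' @export
predict_mz <- function(monomer_mass, n, z, proton_mass = 1.00728, protonated = TRUE) {
  check_number(monomer_mass, "monomer_mass", 0, strict = TRUE)
  if (any(n < 1) || any(z < 1)) abort("`n` and `z` must be >= 1.")
  if (protonated) (n * monomer_mass + z * proton_mass) / z else n * monomer_mass / z
}

#' Estimate the monomer mass from anchor peaks
#'
#' Given anchor peaks with known stoichiometry and charge, solves the
#' weighted least-squares problem `z * mz - z * m_p = n * M` for the monomer
#' mass `M` (a regression through the origin in `n`). The residual scatter
#' yields the standard error; anchors that disagree by more than 0.1% of `M`
#' trigger a warning (broad high-mass peaks), not a failure.
#'
#' @param anchors a data frame with columns `mz`, `n`, `z` (one row per
#'   anchor peak) and optionally `weight`.
#' @param proton_mass,protonated see [predict_mz()].
#' @return object of class `monomer_estimate` with `mass` (Da), `sd`,
#'   `n_anchors` and the per-anchor table (`mz`, `n`, `z`, `implied_mass`,
#'   `residual`).
#' @examples
#' estimate_monomer_mass(data.frame(mz = 34828.6, n = 2, z = 1))
#' @export
estimate_monomer_mass <- function(anchors, proton_mass = 1.00728, protonated = TRUE) {
  stopifnot(is.data.frame(anchors))
  if (!all(c("mz", "n", "z") %in% names(anchors))) {
    abort("`anchors` needs columns mz, n, z.")
  }
  if (nrow(anchors) < 1L) abort("at least one anchor peak is required.")
  a <- as_tibble(anchors)
  if (!"weight" %in% names(a)) a$weight <- rep(1, nrow(a))
  y <- if (protonated) a$z * a$mz - a$z * proton_mass else a$z * a$mz
  m_hat <- sum(a$weight * a$n * y) / sum(a$weight * a$n^2)
  a$implied_mass <- y / a$n
  a$residual <- y - a$n * m_hat
  sd_m <- if (nrow(a) > 1) {
    sqrt(sum(a$weight * a$residual^2) / (nrow(a) - 1) / sum(a$weight * a$n^2))
  } else {
    0
  }
  if (any(abs(a$implied_mass - m_hat) > 1e-3 * m_hat)) {
    warn("inconsistent anchors: some implied monomer masses deviate by > 0.1%.")
  }
  out <- list(mass = m_hat, sd = sd_m, n_anchors = nrow(a), anchors = a)
  class(out) <- "monomer_estimate"
  out
}

#' @export
print.monomer_estimate <- function(x, ...) {
  cat(sprintf("Monomer mass estimate: M = %.2f Da (sd %.3g) from %d anchor peak(s)\n",
              x$mass, x$sd, x$n_anchors))
  invisible(x)
}

#' Assign oligomer stoichiometry and charge to MALDI peaks
#'
#' For each peak, enumerates all `(n <= n_max, z <= z_max)` whose predicted
#' m/z lies within tolerance. The primary assignment is the candidate with
#' the smallest charge, then the smallest stoichiometry (linear-mode MALDI
#' predominantly yields singly charged ions); every other candidate is kept
#' as an alternative and the peak is flagged ambiguous. A two-tier ppm
#' tolerance reflects peak broadening at high mass: `tol_ppm` for
#' `n < n_high`, `tol_ppm_high` for `n >= n_high`. Peaks matching nothing
#' are returned unassigned — a valid outcome, not an error.
#'
#' Note the intrinsic algebraic degeneracy `(2k, 2) ~ (k, 1)`: e.g. a
#' hexamer at `z = 2` lands exactly on the trimer `z = 1` peak.
#'
#' @param peaks a data frame with column `mz` (and optionally `intensity`).
#' @param monomer_mass monomer mass M in Da.
#' @param n_max,z_max enumeration limits (defaults 10 and 3).
#' @param tol_ppm tolerance for low-order oligomers (default 500 ppm).
#' @param tol_ppm_high tolerance for `n >= n_high` (default 2000 ppm).
#' @param n_high first stoichiometry using the high tolerance (default 5).
#' @param proton_mass,protonated see [predict_mz()].
#' @return a tibble with one row per peak: `mz`, `intensity`, primary `n`,
#'   `z`, `predicted_mz`, `error_ppm`, `ambiguous`, `n_candidates` and a
#'   list-column `alternatives` of the non-primary candidates.
#' @examples
#' assign_peaks(data.frame(mz = 52245.1), monomer_mass = 17414)
#' @export
assign_peaks <- function(peaks, monomer_mass, n_max = 10, z_max = 3,
                         tol_ppm = 500, tol_ppm_high = 2000, n_high = 5,
                         proton_mass = 1.00728, protonated = TRUE) {
  stopifnot(is.data.frame(peaks), "mz" %in% names(peaks))
  check_number(monomer_mass, "monomer_mass", 0, strict = TRUE)
  if (any(peaks$mz <= 0)) abort("`mz` must be > 0.")
  pk <- dplyr::arrange(as_tibble(peaks), .data$mz)
  if (!"intensity" %in% names(pk)) pk$intensity <- NA_real_

  cand_grid <- tidyr::expand_grid(n = seq_len(n_max), z = seq_len(z_max))
  cand_grid$predicted_mz <- predict_mz(monomer_mass, cand_grid$n, cand_grid$z,
                                       proton_mass, protonated)
  cand_grid$tol <- ifelse(cand_grid$n >= n_high, tol_ppm_high, tol_ppm)

  rows <- purrr::map(pk$mz, function(mz) {
    err <- (mz - cand_grid$predicted_mz) / cand_grid$predicted_mz * 1e6
    hit <- cand_grid[abs(err) <= cand_grid$tol, ]
    hit$error_ppm <- err[abs(err) <= cand_grid$tol]
    hit <- dplyr::arrange(hit, .data$z, .data$n)
    hit
  })

  pk$n <- purrr::map_int(rows, function(h) if (nrow(h)) h$n[1] else NA_integer_)
  pk$z <- purrr::map_int(rows, function(h) if (nrow(h)) h$z[1] else NA_integer_)
  pk$predicted_mz <- purrr::map_dbl(rows, function(h) if (nrow(h)) h$predicted_mz[1] else NA_real_)
  pk$error_ppm <- purrr::map_dbl(rows, function(h) if (nrow(h)) h$error_ppm[1] else NA_real_)
  pk$n_candidates <- purrr::map_int(rows, nrow)
  pk$ambiguous <- pk$n_candidates > 1L
  pk$alternatives <- purrr::map(rows, function(h) {
    if (nrow(h) > 1) h[-1, c("n", "z", "predicted_mz", "error_ppm")] else
      tibble(n = integer(), z = integer(), predicted_mz = numeric(), error_ppm = numeric())
  })
  pk
}

#' Summarize an oligomer series assignment
#'
#' Tallies which stoichiometries are represented (as primary or alternative
#' assignments), the largest oligomer order seen, per-order ppm accuracy and
#' the list of degenerate `(n, z)` interpretations.
#'
#' @param assignments output of [assign_peaks()].
#' @return object of class `maldi_series` with `stoichiometries` (sorted
#'   integer vector), `n_max`, `per_n` tibble (`n`, `n_peaks`,
#'   `mean_abs_ppm`), `degenerate` tibble of ambiguous peaks, `n_unassigned`.
#' @examples
#' series_report(assign_peaks(data.frame(mz = c(34828.6, 52245.1)), 17414))
#' @export
series_report <- function(assignments) {
  stopifnot(is.data.frame(assignments))
  if (nrow(assignments) == 0L) {
    out <- list(stoichiometries = integer(), n_max = NA_integer_,
                per_n = tibble(n = integer(), n_peaks = integer(), mean_abs_ppm = numeric()),
                degenerate = tibble(), n_unassigned = 0L)
    class(out) <- "maldi_series"
    return(out)
  }
  alts <- dplyr::bind_rows(assignments$alternatives)
  all_n <- c(assignments$n[!is.na(assignments$n)], alts$n)
  per_n <- assignments |>
    dplyr::filter(!is.na(.data$n)) |>
    dplyr::group_by(n = .data$n) |>
    dplyr::summarise(n_peaks = dplyr::n(),
                     mean_abs_ppm = mean(abs(.data$error_ppm)), .groups = "drop")
  degenerate <- assignments |>
    dplyr::filter(.data$ambiguous) |>
    dplyr::select("mz", "n", "z", "n_candidates", "alternatives")
  out <- list(
    stoichiometries = sort(unique(as.integer(all_n))),
    n_max = if (length(all_n)) max(all_n) else NA_integer_,
    per_n = per_n,
    degenerate = degenerate,
    n_unassigned = sum(is.na(assignments$n))
  )
  class(out) <- "maldi_series"
  out
}

#' @export
print.maldi_series <- function(x, ...) {
  cat(sprintf("MALDI oligomer series: stoichiometries {%s}, max n = %s, %d unassigned peak(s)\n",
              paste(x$stoichiometries, collapse = ","),
              as.character(x$n_max), x$n_unassigned))
  if (nrow(x$degenerate)) {
    cat(sprintf("%d peak(s) with degenerate (n, z) interpretations\n", nrow(x$degenerate)))
  }
  invisible(x)
}
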