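#' Candidate oligomer stoichiometries from a molecular-weight ratio
#'
#' Ranks stoichiometries `n = 1..n_max` by the residual `|MW/M - n|`, ties
#' broken toward the smaller `n`. The per-candidate mass residual
#' `|MW - n M| / M` is reported alongside.
#'
#' @param mw_kda assembly molecular weight (kDa, > 0), e.g. from
#'   [volume_to_mw()] or a native-gel band position.
#' @param monomer_kda monomer mass (kDa, > 0), e.g. from
#'   [estimate_monomer_mass()] / 1000.
#' @param n_max largest stoichiometry considered (default 10).
#' @return tibble ranked by fit: `n`, `ratio` (`MW/M`), `residual`
#'   (`|MW/M - n|`), `rank`.
#' @examples
#' stoichiometry_from_mw(82.5, 17.5)  # pentamer then tetramer
#' @export
stoichiometry_from_mw <- function(mw_kda, monomer_kda, n_max = 10) {
  check_number(mw_kda, "mw_kda", 0, strict = TRUE)
  check_number(monomer_kda, "monomer_kda", 0, strict = TRUE)
  n_max <- check_count(n_max, "n_max", 1L)
  ratio <- mw_kda / monomer_kda
  out <- tibble(
    n = seq_len(n_max),
    ratio = ratio,
    residual = abs(ratio - seq_len(n_max))
  )
  out <- out[order(out$residual, out$n), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Rod diameter versus the alpha-helix reference
#'
#' Compares a rod diameter (from [cross_section_guinier()]) with the ~12
#' Angstrom diameter of an alpha-helix. Consistency within the tolerance
#' band supports a cross section of a single helix; a ratio near 2 flags a
#' two-helix (coiled/paired) cross section.
#'
#' @param d rod diameter in Angstrom (> 0).
#' @param helix_diameter reference diameter (default 12 Angstrom).
#' @param tol relative tolerance band (default 0.25).
#' @return tibble with `d`, `helix_diameter`, `ratio`, `consistent`, `tol`.
#' @examples
#' rod_vs_helix(13.7)  # ratio 1.14, consistent
#' @export
rod_vs_helix <- function(d, helix_diameter = 12, tol = 0.25) {
  check_number(d, "d", 0, strict = TRUE)
  ratio <- d / helix_diameter
  tibble(d = d, helix_diameter = helix_diameter, ratio = ratio,
         consistent = abs(ratio - 1) <= tol, tol = tol)
}

#' AFM particle size versus SAXS maximum dimension
#'
#' Compares the full major axis `2 * a1` of the most compact AFM particle
#' class with the SAXS `Dmax` (both nm). Whether the semi- or the full axis
#' corresponds to a "diameter" is genuinely ambiguous; the comparison uses
#' the full axis and prints `a1` itself alongside so it stays auditable. Verdicts: `"matching"` within `tol`, `"borderline"` within
#' `tol + 0.1`, else `"not matching"`.
#'
#' @param a1_nm class mean semi-major axis (nm, > 0).
#' @param dmax_nm SAXS maximum dimension (nm, > 0).
#' @param tol relative tolerance (default 0.35).
#' @return tibble with `a1_nm`, `full_axis_nm`, `dmax_nm`, `ratio`,
#'   `verdict`, `tol`.
#' @examples
#' afm_vs_saxs(14.2, 20.8)  # ratio 1.37: borderline
#' @export
afm_vs_saxs <- function(a1_nm, dmax_nm, tol = 0.35) {
  check_number(a1_nm, "a1_nm", 0, strict = TRUE)
  check_number(dmax_nm, "dmax_nm", 0, strict = TRUE)
  ratio <- 2 * a1_nm / dmax_nm
  dev <- abs(ratio - 1)
  verdict <- if (dev <= tol) "matching" else if (dev <= tol + 0.1) "borderline" else "not matching"
  tibble(a1_nm = a1_nm, full_axis_nm = 2 * a1_nm, dmax_nm = dmax_nm,
         ratio = ratio, verdict = verdict, tol = tol)
}

#' Cross-technique consistency report
#'
#' Assembles whatever evidence is available into a single stoichiometry and
#' dimension reconciliation: MALDI monomer mass, SAXS molecular weight with
#' ranked stoichiometry candidates, rod-diameter versus helix check, AFM
#' versus SAXS dimension match and the ITC temperature trend. Missing
#' techniques are listed, never fatal; a report with no evidence at all is
#' an error. Report generation is pure: identical inputs give identical
#' output.
#'
#' @param maldi optional [estimate_monomer_mass()] result (or a monomer
#'   mass in kDa).
#' @param saxs optional list with any of `mw_kda` (or `volume_nm3`),
#'   `rod_diameter`, `dmax_nm`, `rg`.
#' @param afm optional list with `range_I_a1_nm` (class-I mean semi-major
#'   axis, nm).
#' @param itc optional [temperature_trend()] result.
#' @param n_max stoichiometry search limit.
#' @return object of class `consistency_report`.
#' @examples
#' build_report(maldi = 17.414, saxs = list(volume_nm3 = 105))
#' @export
build_report <- function(maldi = NULL, saxs = NULL, afm = NULL, itc = NULL,
                         n_max = 10) {
  if (is.null(maldi) && is.null(saxs) && is.null(afm) && is.null(itc)) {
    abort("no evidence provided.")
  }
  monomer_kda <- if (inherits(maldi, "monomer_estimate")) maldi$mass / 1000 else maldi
  mw_kda <- NULL
  mw_tbl <- NULL
  if (!is.null(saxs$mw_kda)) {
    mw_kda <- saxs$mw_kda
  } else if (!is.null(saxs$volume_nm3)) {
    mw_tbl <- volume_to_mw(saxs$volume_nm3, saxs$vbar %||% 0.73)
    mw_kda <- mw_tbl$mw_kda
  }
  stoich <- if (!is.null(mw_kda) && !is.null(monomer_kda)) {
    stoichiometry_from_mw(mw_kda, monomer_kda, n_max)
  }
  helix <- if (!is.null(saxs$rod_diameter)) rod_vs_helix(saxs$rod_diameter)
  dim_match <- if (!is.null(afm$range_I_a1_nm) && !is.null(saxs$dmax_nm)) {
    afm_vs_saxs(afm$range_I_a1_nm, saxs$dmax_nm)
  }
  missing <- c("maldi", "saxs", "afm", "itc")[c(is.null(maldi), is.null(saxs),
                                                is.null(afm), is.null(itc))]
  out <- list(
    monomer_kda = monomer_kda,
    mw_kda = mw_kda,
    mw_conversion = mw_tbl,
    stoichiometry = stoich,
    top_stoichiometries = if (!is.null(stoich)) head(stoich$n, 2),
    helix_check = helix,
    dimension_match = dim_match,
    itc_trend = if (inherits(itc, "itc_trend")) itc,
    missing_techniques = missing
  )
  class(out) <- "consistency_report"
  out
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("== Oligomeric-state consistency report ==\n")
  if (!is.null(x$monomer_kda)) cat(sprintf("monomer mass: %.3f kDa\n", x$monomer_kda))
  if (!is.null(x$mw_kda)) cat(sprintf("assembly MW (SAXS): %.1f kDa\n", x$mw_kda))
  if (!is.null(x$stoichiometry)) {
    cat(sprintf("top stoichiometry candidates: n = %s (MW/M = %.2f)\n",
                paste(x$top_stoichiometries, collapse = ", "),
                x$stoichiometry$ratio[1]))
  }
  if (!is.null(x$helix_check)) {
    cat(sprintf("rod diameter %.1f A vs helix %.0f A: ratio %.2f (%s)\n",
                x$helix_check$d, x$helix_check$helix_diameter, x$helix_check$ratio,
                if (x$helix_check$consistent) "consistent" else "inconsistent"))
  }
  if (!is.null(x$dimension_match)) {
    cat(sprintf("AFM 2*a1 = %.1f nm vs SAXS Dmax = %.1f nm: ratio %.2f (%s)\n",
                x$dimension_match$full_axis_nm, x$dimension_match$dmax_nm,
                x$dimension_match$ratio, x$dimension_match$verdict))
  }
  if (!is.null(x$itc_trend)) {
    cat(sprintf("ITC: |Q| ordering %s degC (%s)\n",
                paste(x$itc_trend$ordering, collapse = " > "),
                if (x$itc_trend$strict) "strictly decreasing with T" else "not strict"))
  }
  if (length(x$missing_techniques)) {
    cat("missing techniques:", paste(x$missing_techniques, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a consistency report to JSON
#'
#' @param x a `consistency_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  stopifnot(inherits(x, "consistency_report"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}
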