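# broom-style tidiers for the fitted-result classes

#' Tidy / glance methods for oligostate results
#'
#' `tidy()` returns one row per estimated quantity; `glance()` returns a
#' one-row model-level summary.
#'
#' @param x a fitted result (`guinier_fit`, `cross_section_fit`,
#'   `ift_result`, `form_factor_fit`, `monomer_estimate`, `itc_trend`).
#' @param ... unused.
#' @return a tibble.
#' @name oligostate-tidiers
NULL

#' @rdname oligostate-tidiers
#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble(term = c("rg", "i0"),
         estimate = c(x$rg, x$i0),
         std.error = c(x$rg_sd, NA_real_))
}

#' @rdname oligostate-tidiers
#' @export
glance.guinier_fit <- function(x, ...) {
  tibble(rg = x$rg, i0 = x$i0, q_min = x$q_min, q_max = x$q_max,
         qrg_max = x$qrg_max, n_points = x$n_points)
}

#' @rdname oligostate-tidiers
#' @export
tidy.cross_section_fit <- function(x, ...) {
  tibble(term = c("rc", "diameter"),
         estimate = c(x$rc, x$diameter),
         std.error = c(x$rc_sd, 2 * sqrt(2) * x$rc_sd))
}

#' @rdname oligostate-tidiers
#' @export
glance.cross_section_fit <- function(x, ...) {
  tibble(rc = x$rc, diameter = x$diameter, q_min = x$q_min, q_max = x$q_max,
         n_points = x$n_points)
}

#' @rdname oligostate-tidiers
#' @export
tidy.ift_result <- function(x, ...) x$pr

#' @rdname oligostate-tidiers
#' @export
glance.ift_result <- function(x, ...) {
  tibble(dmax = x$dmax, rg = x$rg, i0 = x$i0, alpha = x$alpha,
         evidence = x$evidence, chisq_red = x$chisq_red,
         n_effective = x$n_effective)
}

#' @rdname oligostate-tidiers
#' @export
tidy.form_factor_fit <- function(x, ...) {
  tibble(term = names(x$params),
         estimate = unlist(x$params),
         fixed = names(x$params) %in% names(x$fixed))
}

#' @rdname oligostate-tidiers
#' @export
glance.form_factor_fit <- function(x, ...) {
  tibble(model = x$model, scale = x$scale, background = x$background,
         chisq_red = x$chisq_red, rg = x$rg,
         n_starts = nrow(x$starts),
         n_converged = sum(x$starts$converged, na.rm = TRUE))
}

#' @rdname oligostate-tidiers
#' @export
tidy.monomer_estimate <- function(x, ...) x$anchors

#' @rdname oligostate-tidiers
#' @export
glance.monomer_estimate <- function(x, ...) {
  tibble(mass = x$mass, sd = x$sd, n_anchors = x$n_anchors)
}

#' @rdname oligostate-tidiers
#' @export
tidy.itc_trend <- function(x, ...) x$summary

#' @rdname oligostate-tidiers
#' @export
glance.itc_trend <- function(x, ...) {
  tibble(monotone = x$monotone, strict = x$strict,
         n_temperatures = nrow(x$summary),
         ordering = paste(x$ordering, collapse = " > "))
}

#' @rdname oligostate-tidiers
#' @export
tidy.dmax_scan <- function(x, ...) x$scores

#' @rdname oligostate-tidiers
#' @export
glance.dmax_scan <- function(x, ...) {
  tibble(best_dmax = x$best_dmax, n_candidates = nrow(x$scores))
}
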