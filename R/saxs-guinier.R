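#' Guinier fit with automatic low-q window selection
#'
#' Fits the Guinier law `ln I = ln I0 - q^2 Rg^2 / 3` by weighted linear
#' regression of `ln I` on `q^2`, restricting the window so that
#' `q_max * Rg <= qrg_limit`. The window is found iteratively: fit on the
#' current window, recompute `Rg`, shrink the upper end until the limit
#' holds; the largest such low-q window is kept.
#'
#' `qrg_limit = 1.3` is the community convention for globular particles; it
#' is configurable (elongated particles often need a smaller limit).
#'
#' @param profile a [saxs_profile()].
#' @param qrg_limit maximum allowed `q * Rg` in the fitted window.
#' @param q_min optional lower bound of the window (1/Angstrom); defaults to
#'   the first data point.
#' @return object of class `guinier_fit` with elements `rg`, `rg_sd`, `i0`,
#'   `q_min`, `q_max`, `qrg_max`, `n_points`, `window` (row indices) and the
#'   underlying `fit`.
#' @examples
#' q <- seq(0.004, 0.2, length.out = 200)
#' p <- saxs_profile(q, guinier_intensity(q, 60), sigma = rep(1e-6, 200))
#' guinier_fit(p)$rg
#' @export
guinier_fit <- function(profile, qrg_limit = 1.3, q_min = NULL) {
  stopifnot(inherits(profile, "data.frame"))
  check_number(qrg_limit, "qrg_limit", 0, strict = TRUE)
  usable <- profile$I > 0 & (is.null(q_min) | profile$q >= (q_min %||% 0))
  idx <- which(usable)
  if (length(idx) < 5L) abort("too few points with I > 0 in the candidate window.")
  w_all <- profile_weights(profile)

  hi <- length(idx)
  rg <- NA_real_
  for (iter in 1:100) {
    win <- idx[seq_len(hi)]
    if (length(win) < 5L) abort("no Guinier region: window shrank below 5 points.")
    q2 <- profile$q[win]^2
    y <- log(profile$I[win])
    # weights for ln I: var(ln I) = (sigma/I)^2
    w <- w_all[win] * profile$I[win]^2
    fit <- lm(y ~ q2, weights = w)
    slope <- coef(fit)[["q2"]]
    if (!is.finite(slope) || slope >= 0) {
      abort("no Guinier region: non-negative slope of ln I vs q^2.")
    }
    rg <- sqrt(-3 * slope)
    hi_new <- max(which(profile$q[idx] * rg <= qrg_limit), 5L)
    hi_new <- min(hi_new, length(idx))
    if (hi_new == hi) break
    hi <- hi_new
  }
  win <- idx[seq_len(hi)]
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["q2"]], error = function(e) NA_real_)
  out <- list(
    rg = rg,
    rg_sd = if (is.finite(se)) se * 3 / (2 * rg) else NA_real_,  # delta method
    i0 = exp(coef(fit)[["(Intercept)"]]),
    q_min = min(profile$q[win]),
    q_max = max(profile$q[win]),
    qrg_max = max(profile$q[win]) * rg,
    qrg_limit = qrg_limit,
    n_points = length(win),
    window = win,
    fit = fit,
    profile = profile
  )
  class(out) <- "guinier_fit"
  out
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "Guinier fit: Rg = %.2f Angstrom (sd %.3g), I0 = %.4g\nwindow q in [%.4g, %.4g] (%d pts), max qRg = %.3f (limit %.2f)\n",
    x$rg, x$rg_sd, x$i0, x$q_min, x$q_max, x$n_points, x$qrg_max, x$qrg_limit
  ))
  invisible(x)
}

#' Cross-sectional Guinier fit for rod-like particles
#'
#' For an elongated particle, `ln(q I(q))` is linear in `q^2` in an
#' intermediate-q regime with slope `-Rc^2 / 2`, where `Rc` is the radius of
#' gyration of the rod cross section. A uniform circular rod of radius `R`
#' has `Rc = R / sqrt(2)`, so the rod diameter is `d = 2 Rc sqrt(2)`.
#'
#' The default window starts at `1/Rg` (rod regime sets in above the overall
#' Guinier region) and its upper end is shrunk until `q_max * Rc <=
#' qrc_limit`, mirroring [guinier_fit()].
#'
#' @param profile a [saxs_profile()].
#' @param q_window optional `c(q_lo, q_hi)` in 1/Angstrom; when `NULL` the
#'   window is chosen automatically as described.
#' @param qrc_limit maximum `q * Rc` in the fitted window (default 1.0).
#' @return object of class `cross_section_fit` with `rc`, `rc_sd`,
#'   `diameter` (`= 2 Rc sqrt(2)`), window metadata and the underlying fit.
#' @examples
#' q <- seq(0.02, 0.35, length.out = 150)
#' p <- saxs_profile(q, exp(-q^2 * 25 / 2) / q, sigma = exp(-q^2 * 25 / 2) / q * 0.01)
#' cross_section_guinier(p, q_window = c(0.02, 0.2))$rc  # 5
#' @export
cross_section_guinier <- function(profile, q_window = NULL, qrc_limit = 1.0) {
  stopifnot(inherits(profile, "data.frame"))
  if (is.null(q_window)) {
    rg_est <- tryCatch(guinier_fit(profile)$rg, error = function(e) NA_real_)
    q_lo <- if (is.finite(rg_est)) 1 / rg_est else min(profile$q)
    q_window <- c(q_lo, max(profile$q))
  }
  idx <- which(profile$q >= q_window[1] & profile$q <= q_window[2] &
                 profile$q * profile$I > 0)
  if (length(idx) < 5L) abort("too few points in the cross-section window.")
  w_all <- profile_weights(profile)

  hi <- length(idx)
  rc <- NA_real_
  for (iter in 1:100) {
    win <- idx[seq_len(hi)]
    if (length(win) < 5L) break
    q2 <- profile$q[win]^2
    y <- log(profile$q[win] * profile$I[win])
    w <- w_all[win] * profile$I[win]^2
    fit <- lm(y ~ q2, weights = w)
    slope <- coef(fit)[["q2"]]
    if (!is.finite(slope) || slope >= 0) {
      abort("no rod-like regime: non-negative slope of ln(qI) vs q^2.")
    }
    rc <- sqrt(-2 * slope)
    hi_new <- max(which(profile$q[idx] * rc <= qrc_limit), 5L)
    hi_new <- min(hi_new, length(idx))
    if (hi_new == hi) break
    hi <- hi_new
  }
  win <- idx[seq_len(hi)]
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["q2"]], error = function(e) NA_real_)
  out <- list(
    rc = rc,
    rc_sd = if (is.finite(se)) se / rc else NA_real_,
    diameter = rod_diameter(rc),
    q_min = min(profile$q[win]),
    q_max = max(profile$q[win]),
    n_points = length(win),
    window = win,
    fit = fit,
    profile = profile
  )
  class(out) <- "cross_section_fit"
  out
}

#' @export
print.cross_section_fit <- function(x, ...) {
  cat(sprintf(
    "Cross-sectional Guinier fit: Rc = %.3f Angstrom (sd %.3g)\nrod diameter 2 Rc sqrt(2) = %.2f Angstrom; window q in [%.4g, %.4g] (%d pts)\n",
    x$rc, x$rc_sd, x$diameter, x$q_min, x$q_max, x$n_points
  ))
  invisible(x)
}

#' Rod diameter implied by a cross-sectional radius of gyration
#'
#' For a uniform circular rod, `d = 2 Rc sqrt(2)`.
#'
#' @param rc cross-sectional radius of gyration (Angstrom).
#' @return diameter in Angstrom.
#' @examples
#' rod_diameter(4.86)  # ~13.7
#' @export
rod_diameter <- function(rc) {
  check_number(rc, "rc", 0, strict = TRUE)
  2 * rc * sqrt(2)
}

#' Dimensionless Kratky transform
#'
#' Computes `x = q Rg`, `y = (q Rg)^2 I(q) / I(0)`. For a compact globular
#' particle the curve peaks at `(sqrt(3), 3/e = 1.104)` — the analytic
#' maximum of `x^2 exp(-x^2/3)`; flexible chains plateau instead. The peak is
#' located by quadratic interpolation through the maximum sample and its two
#' neighbours; a maximum on the boundary of the support is reported as "no
#' interior peak".
#'
#' @param profile a [saxs_profile()].
#' @param guinier a [guinier_fit()] supplying `Rg` and `I(0)`.
#' @return a `kratky_curve` tibble with columns `x`, `y` and attributes
#'   `peak_x`, `peak_y`, `has_peak`, `rg`, `i0`.
#' @examples
#' q <- seq(0.004, 0.2, length.out = 300)
#' p <- saxs_profile(q, guinier_intensity(q, 60), sigma = rep(1e-6, 300))
#' k <- dimensionless_kratky(p, guinier_fit(p))
#' attr(k, "peak_x")  # ~sqrt(3)
#' @export
dimensionless_kratky <- function(profile, guinier) {
  stopifnot(inherits(guinier, "guinier_fit"))
  if (!is.finite(guinier$i0) || guinier$i0 <= 0) abort("guinier$i0 must be > 0.")
  x <- profile$q * guinier$rg
  y <- x^2 * profile$I / guinier$i0
  imax <- which.max(y)
  has_peak <- imax > 1L && imax < length(y)
  if (has_peak) {
    # quadratic through (x_{i-1..i+1}, y_{i-1..i+1})
    xs <- x[(imax - 1):(imax + 1)]
    ys <- y[(imax - 1):(imax + 1)]
    cf <- solve(cbind(1, xs, xs^2), ys)
    peak_x <- -cf[2] / (2 * cf[3])
    peak_y <- cf[1] + cf[2] * peak_x + cf[3] * peak_x^2
  } else {
    peak_x <- NA_real_
    peak_y <- NA_real_
  }
  out <- tibble(x = x, y = y)
  class(out) <- c("kratky_curve", class(out))
  attr(out, "peak_x") <- unname(peak_x)
  attr(out, "peak_y") <- unname(peak_y)
  attr(out, "has_peak") <- has_peak
  attr(out, "rg") <- guinier$rg
  attr(out, "i0") <- guinier$i0
  out
}

#' @export
print.kratky_curve <- function(x, ...) {
  if (isTRUE(attr(x, "has_peak"))) {
    cat(sprintf("<kratky_curve> peak at (qRg = %.3f, %.3f); reference compact point (1.732, 1.104)\n",
                attr(x, "peak_x"), attr(x, "peak_y")))
  } else {
    cat("<kratky_curve> no interior peak (monotone curve)\n")
  }
  NextMethod()
}
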