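# ggplot2 autoplot methods for the main result types

#' Plot methods for oligostate objects
#'
#' `autoplot()` methods returning ggplot objects: log-log scattering
#' profiles, Guinier diagnostics (ln I vs q^2 with the fitted window),
#' dimensionless Kratky curves with the compact-particle reference point,
#' P(r) distributions, form-factor fits with residuals, AFM height maps and
#' ITC thermograms.
#'
#' @param object the result object.
#' @param ... unused.
#' @return a ggplot.
#' @name oligostate-autoplot
NULL

#' @rdname oligostate-autoplot
#' @export
autoplot.saxs_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$I)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ ("Å"^-1)), y = "I(q)") +
    ggplot2::theme_minimal()
}

#' @rdname oligostate-autoplot
#' @export
autoplot.guinier_fit <- function(object, ...) {
  prof <- object$profile
  df <- tibble(q2 = prof$q^2, lnI = suppressWarnings(log(prof$I)),
               in_window = seq_len(nrow(prof)) %in% object$window)
  df <- df[is.finite(df$lnI), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q2, y = .data$lnI, colour = .data$in_window)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(intercept = log(object$i0), slope = -object$rg^2 / 3,
                         linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00", `FALSE` = "grey60"),
                                 name = "Guinier window") +
    ggplot2::labs(x = expression(q^2 ~ ("Å"^-2)), y = "ln I(q)",
                  subtitle = sprintf("Rg = %.1f Å, qRg ≤ %.2f", object$rg, object$qrg_limit)) +
    ggplot2::theme_minimal()
}

#' @rdname oligostate-autoplot
#' @export
autoplot.kratky_curve <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = sqrt(3), linetype = 3) +
    ggplot2::geom_hline(yintercept = 3 / exp(1), linetype = 3) +
    ggplot2::labs(x = expression(q ~ R[g]), y = expression((q ~ R[g])^2 ~ I(q) / I(0)),
                  subtitle = "dotted: compact-particle reference (√3, 1.104)") +
    ggplot2::coord_cartesian(xlim = c(0, min(max(object$x), 10))) +
    ggplot2::theme_minimal()
  if (isTRUE(attr(object, "has_peak"))) {
    p <- p + ggplot2::annotate("point", x = attr(object, "peak_x"),
                               y = attr(object, "peak_y"), colour = "#D55E00")
  }
  p
}

#' @rdname oligostate-autoplot
#' @export
autoplot.ift_result <- function(object, ...) {
  ggplot2::ggplot(object$pr, ggplot2::aes(x = .data$r, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "r (Å)", y = "P(r)",
                  subtitle = sprintf("Dmax = %g Å, real-space Rg = %.1f Å",
                                     object$dmax, object$rg)) +
    ggplot2::theme_minimal()
}

#' @rdname oligostate-autoplot
#' @export
autoplot.form_factor_fit <- function(object, ...) {
  prof <- object$profile
  df <- tibble(q = prof$q, I = prof$I, fitted = object$fitted,
               resid = (prof$I - object$fitted) / profile_sigma(prof))
  top <- ggplot2::ggplot(df, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$I), size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#0072B2") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "I(q)",
                  subtitle = sprintf("%s fit, reduced chi^2 = %.2f", object$model, object$chisq_red)) +
    ggplot2::theme_minimal()
  bottom <- ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$resid)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(q ~ ("Å"^-1)), y = "(I - fit)/σ") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(top, bottom, ncol = 1, heights = c(3, 1))
  } else {
    top
  }
}

#' @rdname oligostate-autoplot
#' @export
autoplot.afm_heightmap <- function(object, ...) {
  df <- tidyr::expand_grid(x = seq_len(nrow(object$heights)),
                           y = seq_len(ncol(object$heights)))
  df$height <- object$heights[cbind(df$x, df$y)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x * object$pixel_size,
                                   y = .data$y * object$pixel_size,
                                   fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "z (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' @rdname oligostate-autoplot
#' @export
autoplot.itc_thermogram <- function(object, ...) {
  inj <- attr(object, "injections")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$time_s, y = .data$power_uW)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = inj$time_s, linetype = 3, colour = "grey60") +
    ggplot2::labs(x = "time (s)", y = "differential power (µW)",
                  subtitle = sprintf("%g °C", attr(object, "temperature"))) +
    ggplot2::theme_minimal()
}

#' @rdname oligostate-autoplot
#' @export
autoplot.itc_trend <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$temperature, y = .data$total_abs_uJ)) +
    ggplot2::geom_col(width = 2, fill = "#0072B2") +
    ggplot2::labs(x = "temperature (°C)", y = "total |Q| (µJ)") +
    ggplot2::theme_minimal()
}
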