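#' Fit an analytic form-factor model to a scattering profile
#'
#' Weighted least squares of `scale * model(q; shape) + background` against
#' the measured intensities. The linear parameters (scale, background) are
#' profiled out analytically at every evaluation, so the optimizer only
#' searches the shape parameters. To avoid local minima, Nelder-Mead is
#' started from a coarse grid of at least five starting points spanning the
#' bounds; all per-start results are retained for diagnostics.
#'
#' Any shape parameter can be held fixed through `fixed` — e.g. fitting an
#' elliptical cylinder with its length fixed to a thickness known from a
#' complementary technique (AFM) while the cross-section axes are optimized.
#'
#' @param profile a [saxs_profile()].
#' @param model `"sphere"`, `"cylinder"` or `"elliptical_cylinder"`.
#' @param fixed named list of parameters to hold fixed, e.g. `list(l = 16)`.
#' @param bounds named list of `c(lo, hi)` for each free parameter;
#'   defaults span 10-300 Angstrom for lengths and 1-3 for the axis ratio.
#' @param n_starts minimum number of multi-start points (default 6).
#' @param n_quad quadrature order passed to the model evaluator.
#' @param background fit a constant background? (default TRUE)
#' @return object of class `form_factor_fit` with `model`, `params` (all
#'   shape parameters, fitted and fixed), `fixed`, `scale`, `background`,
#'   `chisq_red`, `rg` (closed-form Rg at the fitted shape), `fitted`,
#'   `starts` (per-start diagnostics tibble).
#' @examples
#' \donttest{
#' q <- seq(0.006, 0.25, length.out = 80)
#' p <- saxs_profile(q, elliptical_cylinder_intensity(q, 77, 1.2, 16))
#' fit_form_factor(p, "elliptical_cylinder", fixed = list(l = 16))
#' }
#' @export
fit_form_factor <- function(profile, model = "elliptical_cylinder",
                            fixed = list(), bounds = NULL, n_starts = 6,
                            n_quad = 76, background = TRUE) {
  stopifnot(inherits(profile, "data.frame"))
  all_pars <- switch(model,
    sphere = "r",
    cylinder = c("r", "l"),
    elliptical_cylinder = c("a", "nu", "l"),
    abort(sprintf("unknown model '%s'", model))
  )
  if (length(setdiff(names(fixed), all_pars)) > 0) {
    abort("`fixed` names unknown parameters for this model.")
  }
  free <- setdiff(all_pars, names(fixed))
  if (length(free) < 1L) abort("at least one free shape parameter is required.")

  default_bounds <- list(r = c(10, 300), a = c(10, 300), l = c(5, 500), nu = c(1, 3))
  bounds <- modifyList(default_bounds[free], bounds %||% list())
  if (any(!vapply(bounds[free], function(b) all(is.finite(b)), logical(1)))) {
    abort("bounds must be finite.")
  }

  y <- profile$I
  w <- profile_weights(profile)
  q <- profile$q

  # chi^2 with (scale, background) profiled out by weighted linear LS
  eval_chisq <- function(theta) {
    params <- c(as.list(setNames(theta, free)), fixed)
    mi <- model_intensity(model, q, params, n_quad)
    X <- if (background) cbind(mi, 1) else cbind(mi)
    XtW <- t(X * w)
    beta <- tryCatch(solve(XtW %*% X, XtW %*% y), error = function(e) NULL)
    if (is.null(beta) || beta[1] <= 0) {
      # degenerate model curve; fall back to scale-only LS
      beta <- c(max(sum(w * mi * y) / sum(w * mi^2), 1e-12), 0)[1:ncol(X)]
    }
    res <- y - X %*% beta
    list(chisq = sum(w * res^2), beta = beta, fitted = drop(X %*% beta))
  }

  # log-transform lengths, logit-like transform for nu to respect bounds
  to_unconstrained <- function(theta) {
    vapply(seq_along(free), function(i) {
      b <- bounds[[free[i]]]
      stats::qlogis((theta[i] - b[1]) / (b[2] - b[1]))
    }, numeric(1))
  }
  to_constrained <- function(u) {
    vapply(seq_along(free), function(i) {
      b <- bounds[[free[i]]]
      b[1] + (b[2] - b[1]) * stats::plogis(u[i])
    }, numeric(1))
  }
  objective <- function(u) eval_chisq(to_constrained(u))$chisq

  # coarse multi-start grid across the bounds
  grid_1d <- function(b, k) b[1] + (b[2] - b[1]) * seq(0.15, 0.85, length.out = k)
  k <- max(2L, ceiling(n_starts^(1 / length(free))))
  starts <- expand.grid(lapply(free, function(p) grid_1d(bounds[[p]], k)))
  names(starts) <- free
  if (nrow(starts) > max(n_starts, 12L)) starts <- starts[seq_len(max(n_starts, 12L)), , drop = FALSE]

  # stage 1: score every start (one model evaluation each)
  start_chisq <- vapply(seq_len(nrow(starts)), function(i) {
    tryCatch(eval_chisq(as.numeric(starts[i, ]))$chisq, error = function(e) Inf)
  }, numeric(1))
  if (all(!is.finite(start_chisq))) {
    abort("form-factor fit failed to converge from any start; see per-start diagnostics.")
  }
  # stage 2: Nelder-Mead polish from the two most promising starts
  polish_idx <- utils::head(order(start_chisq), 2L)
  runs <- purrr::map_dfr(seq_len(nrow(starts)), function(i) {
    th0 <- as.numeric(starts[i, ])
    base <- tibble(start = i, start_chisq = start_chisq[i],
                   !!!setNames(as.list(th0), paste0("start_", free)))
    if (!(i %in% polish_idx)) {
      return(dplyr::mutate(base, chisq = start_chisq[i], converged = NA,
                           !!!setNames(as.list(rep(NA_real_, length(free))), free)))
    }
    opt <- tryCatch(
      optim(to_unconstrained(th0), objective, method = "Nelder-Mead",
            control = list(maxit = 300, reltol = 1e-9)),
      error = function(e) NULL
    )
    if (is.null(opt)) {
      return(dplyr::mutate(base, chisq = Inf, converged = FALSE,
                           !!!setNames(as.list(rep(NA_real_, length(free))), free)))
    }
    th <- to_constrained(opt$par)
    dplyr::mutate(base, chisq = opt$value, converged = opt$convergence == 0,
                  !!!setNames(as.list(th), free))
  })
  polished <- runs[runs$start %in% polish_idx & is.finite(runs$chisq), ]
  if (nrow(polished) == 0L) {
    abort("form-factor fit failed to converge from any start; see per-start diagnostics.")
  }
  best <- polished[which.min(polished$chisq), ]
  theta <- unname(unlist(best[1, free]))
  final <- eval_chisq(theta)
  params <- c(as.list(setNames(theta, free)), fixed)

  n_par <- length(free) + 1L + as.integer(background)
  dof <- max(nrow(profile) - n_par, 1L)
  rg <- tryCatch(model_rg(model, params), error = function(e) NA_real_)
  out <- list(
    model = model,
    params = params[all_pars],
    free = free,
    fixed = fixed,
    scale = final$beta[1],
    background = if (background) final$beta[2] else 0,
    chisq = final$chisq,
    chisq_red = final$chisq / dof,
    rg = rg,
    fitted = final$fitted,
    starts = runs,
    bounds = bounds,
    profile = profile,
    n_quad = n_quad
  )
  class(out) <- "form_factor_fit"
  out
}

#' @export
print.form_factor_fit <- function(x, ...) {
  par_str <- paste(sprintf("%s = %.4g%s", names(x$params), unlist(x$params),
                           ifelse(names(x$params) %in% names(x$fixed), " (fixed)", "")),
                   collapse = ", ")
  cat(sprintf(
    "Form-factor fit (%s): %s\nscale = %.4g, background = %.4g, reduced chi^2 = %.3f, model Rg = %.2f Angstrom\n",
    x$model, par_str, x$scale, x$background, x$chisq_red, x$rg
  ))
  invisible(x)
}
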