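#' Simulate a 1-D SAXS profile from an analytic shape model
#'
#' Evaluates one of the package's form-factor models on a q grid, scales by
#' `i0`, and applies multiplicative Gaussian noise: `I = I_model * (1 + eps)`
#' with `eps ~ N(0, frac_sd)`. The reported uncertainty column is
#' `sigma = frac_sd * I_model`, the relative-error model typical of
#' azimuthally averaged synchrotron data. With `frac_sd = 0` the profile is
#' the exact model curve (sigma all zero; downstream fits then fall back to
#' conventional 2% weights).
#'
#' @param model `"guinier"`, `"sphere"`, `"cylinder"` or
#'   `"elliptical_cylinder"`.
#' @param params named list of shape parameters (see [form_factors]).
#' @param q strictly increasing positive q grid (1/Angstrom).
#' @param i0 forward scattering scale (default 1).
#' @param frac_sd fractional noise sd per point (default 0.02, the module's
#'   default instrument noise; >= 0).
#' @param seed integer seed for reproducibility (`NULL` = ambient RNG).
#' @return a [saxs_profile()].
#' @examples
#' simulate_saxs("guinier", list(rg = 60), q = seq(0.005, 0.2, 0.005), frac_sd = 0)
#' @export
simulate_saxs <- function(model, params, q, i0 = 1, frac_sd = 0.02, seed = NULL) {
  check_number(i0, "i0", 0, strict = TRUE)
  check_number(frac_sd, "frac_sd", 0)
  if (any(q <= 0) || any(diff(q) <= 0)) abort("`q` must be positive and strictly increasing.")
  base <- i0 * model_intensity(model, q, params)
  eps <- if (frac_sd > 0) {
    with_seed_or_not(seed, rnorm(length(q), 0, frac_sd))
  } else {
    numeric(length(q))
  }
  saxs_profile(q, base * (1 + eps), sigma = frac_sd * base)
}

#' Simulate a MALDI-TOF oligomer peak list
#'
#' One peak per stoichiometry/charge combination at
#' `m/z = (n * M + z * m_p) / z` (protonated-ion convention, proton mass
#' 1.00728 Da), with optional per-peak Gaussian mass jitter in ppm and
#' intensities decaying geometrically with oligomer order — the usual
#' appearance of a non-covalent oligomer ladder in linear positive mode.
#' Peaks are delta-like (a list, not a rendered continuum), which is what
#' series-matching analysis consumes.
#'
#' @param monomer_mass monomer average mass M in Da (> 0).
#' @param n integer vector of stoichiometries (>= 1), default dimer-heptamer.
#' @param z integer vector of charge states (>= 1), default 1:2.
#' @param mass_error_ppm sd of the Gaussian m/z jitter in ppm (>= 0).
#' @param intensity_decay multiplicative intensity factor per oligomer order
#'   (default 0.55).
#' @param proton_mass proton mass in Da.
#' @param protonated if FALSE, peaks are bare `n*M/z` (no proton adduct).
#' @param seed integer seed (`NULL` = ambient RNG).
#' @return a tibble with `mz`, `intensity` and ground-truth `n_true`,
#'   `z_true`, sorted by `mz`.
#' @examples
#' simulate_maldi(17413.8, n = 2:4, z = 1, mass_error_ppm = 0)
#' @export
simulate_maldi <- function(monomer_mass, n = 2:7, z = 1:2, mass_error_ppm = 0,
                           intensity_decay = 0.55, proton_mass = 1.00728,
                           protonated = TRUE, seed = NULL) {
  check_number(monomer_mass, "monomer_mass", 0, strict = TRUE)
  check_number(mass_error_ppm, "mass_error_ppm", 0)
  if (any(n < 1) || any(n != round(n))) abort("`n` must be integers >= 1.")
  if (any(z < 1) || any(z != round(z))) abort("`z` must be integers >= 1.")
  grid <- tidyr::expand_grid(n_true = as.integer(n), z_true = as.integer(z))
  mz0 <- predict_mz(monomer_mass, grid$n_true, grid$z_true,
                    proton_mass = proton_mass, protonated = protonated)
  jit <- if (mass_error_ppm > 0) {
    with_seed_or_not(seed, rnorm(nrow(grid), 0, mass_error_ppm * 1e-6))
  } else {
    numeric(nrow(grid))
  }
  out <- grid
  out$mz <- mz0 * (1 + jit)
  out$intensity <- intensity_decay^(out$n_true - 1) / out$z_true
  dplyr::arrange(out[c("mz", "intensity", "n_true", "z_true")], .data$mz)
}

#' Built-in AFM particle classes (morphometric reference table)
#'
#' Per-class ellipse morphometry of IBP oligomer particles on mica: Gaussian
#' mean and sd of the semi-major axis `a1`, semi-minor axis `a2`, axis ratio,
#' square-root area `s` and height `z` (all nm), together with the
#' semi-major-axis window defining each class. Classes I and II overlap on
#' 17-20 nm by construction. This table drives the default settings of
#' [simulate_afm()] and the default class windows of [segment_ranges()].
#'
#' @return a tibble with one row per class (I-IV).
#' @examples
#' afm_particle_classes()
#' @export
afm_particle_classes <- function() {
  tibble(
    range = c("I", "II", "III", "IV"),
    a1_min = c(5, 17, 28, 44),
    a1_max = c(20, 27, 44, 60),
    a1_mean = c(14.2, 24.0, 32.8, 51.1),
    a1_sd = c(3.9, 2.5, 4.6, 4.9),
    a2_mean = c(10.5, 18.6, 20.5, 27.5),
    a2_sd = c(2.8, 1.5, 2.7, 7.8),
    ratio_mean = c(1.4, 1.3, 1.5, 1.86),
    ratio_sd = c(0.2, 0.1, 0.2, 0.5),
    s_mean = c(20.1, 36.3, 44.3, 60.5),
    s_sd = c(5.5, 3.0, 4.2, 10.1),
    z_mean = c(1.57, 1.86, 2.43, 1.90),
    z_sd = c(0.31, 0.46, 0.74, 0.47)
  )
}

#' Simulate an AFM height map of elliptical-cap particles
#'
#' Renders `n` particles as smooth elliptical caps,
#' `h(x, y) = z * max(0, 1 - (x'/a1)^2 - (y'/a2)^2)`
#' in particle-centred rotated coordinates, on a rough background of i.i.d.
#' Gaussian noise. Per-particle parameters `(a1, a2, z)` are drawn from
#' truncated (> 0) Gaussians; `a1 >= a2` is enforced by swapping. Particles
#' are placed on a jittered square grid with uniformly random orientations,
#' which guarantees non-overlap and keeps every particle clear of the image
#' border; the image size is derived from `n` and the largest sampled `a1`
#' unless given.
#'
#' @param n number of particles (>= 0).
#' @param a1_mean,a1_sd,a2_mean,a2_sd,z_mean,z_sd Gaussian parameters of the
#'   semi-axes and height (nm); defaults are the class-I values of
#'   [afm_particle_classes()].
#' @param pixel_size lateral sampling in nm per pixel (> 0).
#' @param background_sd background roughness sd in nm (default 0.05).
#' @param image_size optional edge length in pixels; computed when `NULL`.
#' @param seed integer seed (`NULL` = ambient RNG).
#' @return a list with `map` (an [afm_heightmap()]) and `truth` (tibble of
#'   ground-truth particle parameters: `a1`, `a2`, `ratio`, `z`, centroid in
#'   px, `theta` orientation in rad).
#' @examples
#' sim <- simulate_afm(5, seed = 1)
#' dim(sim$map$heights)
#' @export
simulate_afm <- function(n, a1_mean = 14.2, a1_sd = 3.9, a2_mean = 10.5,
                         a2_sd = 2.8, z_mean = 1.57, z_sd = 0.31,
                         pixel_size = 1, background_sd = 0.05,
                         image_size = NULL, seed = NULL) {
  n <- check_count(n, "n", 0L)
  check_number(pixel_size, "pixel_size", 0, strict = TRUE)
  check_number(background_sd, "background_sd", 0)
  with_seed_or_not(seed, {
    rtnorm <- function(k, mean, sd) {
      x <- rnorm(k, mean, sd)
      while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), mean, sd)
      x
    }
    a1 <- rtnorm(n, a1_mean, a1_sd)
    a2 <- rtnorm(n, a2_mean, a2_sd)
    swap <- a2 > a1
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    z <- rtnorm(n, z_mean, z_sd)
    theta <- runif(n, 0, pi)

    # jittered-grid placement: one particle per cell, fully inside its cell
    clearance <- 4 * pixel_size
    cell_nm <- if (n > 0) 2 * max(a1) + 2 * clearance else 10
    cell_px <- ceiling(cell_nm / pixel_size)
    k <- ceiling(sqrt(max(n, 1)))
    npx <- if (is.null(image_size)) k * cell_px + 2L else as.integer(image_size)
    if (!is.null(image_size) && n > 0 && k * cell_px + 2L > npx) {
      abort("particles do not fit: image_size too small for n particles of this size.")
    }
    heights <- matrix(
      if (background_sd > 0) rnorm(npx * npx, 0, background_sd) else 0,
      npx, npx
    )

    if (n > 0) {
      cells <- sample.int(k * k, n)                     # random cell order
      cx <- cy <- numeric(n)
      for (i in seq_len(n)) {
        ci <- (cells[i] - 1) %% k
        cj <- (cells[i] - 1) %/% k
        half <- a1[i] / pixel_size + 1
        lo_x <- ci * cell_px + 1 + half
        hi_x <- (ci + 1) * cell_px - half
        lo_y <- cj * cell_px + 1 + half
        hi_y <- (cj + 1) * cell_px - half
        cx[i] <- runif(1, min(lo_x, hi_x), max(lo_x, hi_x))
        cy[i] <- runif(1, min(lo_y, hi_y), max(lo_y, hi_y))
        heights <- render_cap(heights, cx[i], cy[i], a1[i] / pixel_size,
                              a2[i] / pixel_size, z[i], theta[i])
      }
      truth <- tibble(a1 = a1, a2 = a2, ratio = a1 / a2, z = z,
                      x_px = cx, y_px = cy, theta = theta)
    } else {
      truth <- tibble(a1 = numeric(), a2 = numeric(), ratio = numeric(),
                      z = numeric(), x_px = numeric(), y_px = numeric(),
                      theta = numeric())
    }
    list(map = afm_heightmap(heights, pixel_size), truth = truth)
  })
}

# add one elliptical cap to a height matrix (max-composited); axes in px
render_cap <- function(heights, cx, cy, a1_px, a2_px, z, theta) {
  half <- ceiling(a1_px) + 1
  xs <- max(1, floor(cx - half)):min(nrow(heights), ceiling(cx + half))
  ys <- max(1, floor(cy - half)):min(ncol(heights), ceiling(cy + half))
  dx <- outer(xs - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - cy)
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  cap <- z * pmax(0, 1 - (xr / a1_px)^2 - (yr / a2_px)^2)
  heights[xs, ys] <- heights[xs, ys] + cap
  heights
}

#' Simulate an ITC dissociation thermogram
#'
#' Builds a differential-power trace as baseline drift plus one
#' single-exponential response peak per injection,
#' `p(t) = (Q / tau) * exp(-(t - t_inj) / tau)` for `t >= t_inj`,
#' so each peak's time integral equals its specified heat `Q` — the standard
#' response kernel of a power-compensation calorimeter (only the integrals
#' matter downstream). Gaussian instrument noise is added per sample.
#'
#' @param heats per-injection heats in microjoules (signed; exothermic
#'   injections negative by the usual convention).
#' @param injection_times injection times in seconds (default 300 s spacing
#'   starting at 300 s).
#' @param tau response time constant in seconds (default 15).
#' @param baseline_drift linear baseline drift in microwatt/s (default 0).
#' @param noise_sd instrument noise sd in microwatt (default 0.02).
#' @param dt sampling interval in seconds (default 1).
#' @param t_end trace end time; defaults to last injection + 300 s.
#' @param temperature cell temperature label in Celsius.
#' @param seed integer seed (`NULL` = ambient RNG).
#' @return an [itc_thermogram()].
#' @examples
#' tg <- simulate_itc(heats = rep(-10, 3), noise_sd = 0)
#' @export
simulate_itc <- function(heats, injection_times = NULL, tau = 15,
                         baseline_drift = 0, noise_sd = 0.02, dt = 1,
                         t_end = NULL, temperature = 25, seed = NULL) {
  check_number(tau, "tau", 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  check_number(dt, "dt", 0, strict = TRUE)
  n_inj <- length(heats)
  if (is.null(injection_times)) {
    injection_times <- if (n_inj > 0) seq(300, by = 300, length.out = n_inj) else numeric()
  }
  if (length(injection_times) != n_inj) {
    abort("`injection_times` must match `heats` in length.")
  }
  t_end <- t_end %||% if (n_inj > 0) max(injection_times) + 300 else 600
  time <- seq(0, t_end, by = dt)
  power <- baseline_drift * time
  for (i in seq_len(n_inj)) {
    on <- time >= injection_times[i]
    power[on] <- power[on] +
      (heats[i] / tau) * exp(-(time[on] - injection_times[i]) / tau)
  }
  if (noise_sd > 0) {
    power <- power + with_seed_or_not(seed, rnorm(length(time), 0, noise_sd))
  }
  itc_thermogram(time, power, injection_times, temperature = temperature)
}
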