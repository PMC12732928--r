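#' Analytic small-angle scattering form factors
#'
#' Normalized (I(0) = 1) orientationally averaged single-particle scattering
#' intensities for the shape models used throughout the SAXS pipeline.
#'
#' * `guinier_intensity()` — the Guinier law `exp(-q^2 Rg^2 / 3)`, the
#'   low-q limit of any compact particle.
#' * `sphere_intensity()` — homogeneous sphere of radius `r`:
#'   `[3 (sin(qr) - qr cos(qr)) / (qr)^3]^2`.
#' * `cylinder_intensity()` — homogeneous circular cylinder (radius `r`,
#'   length `l`), orientationally averaged by Gauss-Legendre quadrature over
#'   the angle between the cylinder axis and the momentum transfer.
#' * `elliptical_cylinder_intensity()` — cylinder with elliptical cross
#'   section: semi-minor axis `a`, semi-major axis `nu * a` (`nu >= 1`),
#'   length `l`. The amplitude for orientation `(alpha, psi)` is
#'   `2 J1(u)/u * sinc(q l cos(alpha) / 2)` with
#'   `u = q sin(alpha) a sqrt(cos(psi)^2 + nu^2 sin(psi)^2)`; the intensity
#'   is the double quadrature of the squared amplitude over both angles.
#'
#' All lengths are in Angstrom and `q` in 1/Angstrom.
#'
#' @param q numeric vector of momentum transfer values (1/Angstrom), `>= 0`.
#' @param rg radius of gyration (Angstrom).
#' @param r sphere / cylinder radius (Angstrom).
#' @param a semi-minor axis of the elliptical cross section (Angstrom).
#' @param nu axis ratio (semi-major / semi-minor), `>= 1`.
#' @param l cylinder length (Angstrom).
#' @param n_quad Gauss-Legendre order per angular axis (default 76).
#' @return numeric vector of intensities, `I(0) = 1`.
#' @examples
#' q <- seq(0.005, 0.3, length.out = 50)
#' plot(q, sphere_intensity(q, r = 30), log = "y", type = "l")
#' @name form_factors
NULL

#' @rdname form_factors
#' @export
guinier_intensity <- function(q, rg) {
  check_number(rg, "rg", 0, strict = TRUE)
  exp(-q^2 * rg^2 / 3)
}

#' @rdname form_factors
#' @export
sphere_intensity <- function(q, r) {
  check_number(r, "r", 0, strict = TRUE)
  x <- q * r
  out <- ifelse(
    x < 1e-3,
    1 - x^2 / 5 + 3 * x^4 / 175,            # series limit, avoids cancellation
    (3 * (sin(x) - x * cos(x)) / x^3)^2
  )
  as.numeric(out)
}

#' @rdname form_factors
#' @export
cylinder_intensity <- function(q, r, l, n_quad = 76) {
  check_number(r, "r", 0, strict = TRUE)
  check_number(l, "l", 0, strict = TRUE)
  gl <- pracma::gaussLegendre(n_quad, 0, pi / 2)
  sa <- sin(gl$x)
  ca <- cos(gl$x)
  # amplitude on the q x alpha grid
  u <- outer(q, sa) * r                     # nq x n_quad
  v <- outer(q, ca) * l / 2
  amp <- bessel_ratio(u) * sinc(v)
  raw <- drop((amp^2 * rep(sa, each = length(q))) %*% gl$w)
  raw / sum(gl$w * sa)                      # I(0) = 1
}

#' @rdname form_factors
#' @export
elliptical_cylinder_intensity <- function(q, a, nu, l, n_quad = 76) {
  check_number(a, "a", 0, strict = TRUE)
  check_number(l, "l", 0, strict = TRUE)
  check_number(nu, "nu", 1)
  gl_a <- pracma::gaussLegendre(n_quad, 0, pi / 2)   # alpha: axis tilt
  gl_p <- pracma::gaussLegendre(n_quad, 0, pi / 2)   # psi: cross-section azimuth
  sa <- sin(gl_a$x)
  g <- sqrt(cos(gl_p$x)^2 + nu^2 * sin(gl_p$x)^2)
  nq <- length(q)
  qsa <- outer(q, sa)                                # nq x n_quad
  axial <- sinc(outer(q, cos(gl_a$x)) * l / 2)       # nq x n_quad
  acc <- matrix(0, nq, n_quad)
  for (j in seq_len(n_quad)) {                       # loop over psi
    u <- qsa * (a * g[j])
    acc <- acc + gl_p$w[j] * bessel_ratio(u)^2
  }
  raw <- (acc * axial^2 * rep(sa, each = nq)) %*% gl_a$w
  # normalize to I(0) = 1: at q = 0 the integrand is sin(alpha) * sum(w_psi)
  norm <- sum(gl_p$w) * sum(gl_a$w * sa)
  drop(raw) / norm
}

# 2 J1(u) / u with the u -> 0 limit of 1
bessel_ratio <- function(u) {
  out <- u
  small <- abs(u) < 1e-6
  out[small] <- 1 - u[small]^2 / 8
  out[!small] <- 2 * besselJ(u[!small], 1) / u[!small]
  out
}

#' Radius of gyration of an analytic shape model
#'
#' Closed forms: sphere `r sqrt(3/5)`; (elliptical) cylinder with semi-axes
#' `a`, `b = nu a` and length `l`: `sqrt((a^2 + b^2)/4 + l^2/12)` (a circular
#' cylinder is the `nu = 1` case).
#'
#' @param model one of `"sphere"`, `"cylinder"`, `"elliptical_cylinder"`,
#'   `"guinier"`.
#' @param params named list of shape parameters: `r` (sphere/cylinder
#'   radius), `a`, `nu`, `l` (cylinders), `rg` (guinier).
#' @return radius of gyration in Angstrom.
#' @examples
#' model_rg("elliptical_cylinder", list(a = 77, nu = 1.2, l = 16))  # ~60.3
#' @export
model_rg <- function(model, params) {
  switch(model,
    sphere = {
      check_number(params$r, "r", 0, strict = TRUE)
      params$r * sqrt(3 / 5)
    },
    guinier = {
      check_number(params$rg, "rg", 0, strict = TRUE)
      params$rg
    },
    cylinder = {
      check_number(params$r, "r", 0, strict = TRUE)
      check_number(params$l, "l", 0)
      sqrt(params$r^2 / 2 + params$l^2 / 12)
    },
    elliptical_cylinder = {
      check_number(params$a, "a", 0, strict = TRUE)
      check_number(params$nu, "nu", 1)
      check_number(params$l, "l", 0)
      b <- params$a * params$nu
      sqrt((params$a^2 + b^2) / 4 + params$l^2 / 12)
    },
    abort(sprintf("unknown model '%s'", model))
  )
}

# evaluate a named model on q given a parameter list (used by the simulator
# and the form-factor fitter)
model_intensity <- function(model, q, params, n_quad = 76) {
  switch(model,
    guinier = guinier_intensity(q, params$rg),
    sphere = sphere_intensity(q, params$r),
    cylinder = cylinder_intensity(q, params$r, params$l, n_quad),
    elliptical_cylinder =
      elliptical_cylinder_intensity(q, params$a, params$nu, params$l, n_quad),
    abort(sprintf("unknown model '%s'", model))
  )
}

#' Molecular weight from an excluded volume
#'
#' Converts a particle excluded volume (nm^3) to a molecular weight using the
#' protein partial specific volume: `MW[kDa] = V[nm^3] * N_A / (vbar * 1e24)`,
#' i.e. a divisor of ~1.212 nm^3/kDa at the protein default
#' `vbar = 0.73 cm^3/g`. Both the weight and the divisor are returned so the
#' conversion convention is auditable.
#'
#' @param volume_nm3 excluded volume in nm^3 (> 0).
#' @param vbar partial specific volume in cm^3/g (default 0.73, typical for
#'   globular proteins).
#' @return a tibble with `volume_nm3`, `vbar`, `divisor_nm3_per_kda`,
#'   `mw_kda`.
#' @examples
#' volume_to_mw(105)  # ~86.6 kDa
#' @export
volume_to_mw <- function(volume_nm3, vbar = 0.73) {
  check_number(volume_nm3, "volume_nm3", 0, strict = TRUE)
  check_number(vbar, "vbar", 0, strict = TRUE)
  avogadro <- 6.02214076e23
  # V[nm^3] * 1e-21 cm^3 / vbar -> g per particle; * N_A -> g/mol; /1e3 -> kDa
  divisor <- vbar * 1e21 / avogadro * 1e3   # nm^3 per kDa
  tibble(
    volume_nm3 = volume_nm3,
    vbar = vbar,
    divisor_nm3_per_kda = divisor,
    mw_kda = volume_nm3 / divisor
  )
}
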