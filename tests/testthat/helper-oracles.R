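# independent closed-form oracles used across tests

# sphere form factor, written out independently of the package
oracle_sphere <- function(q, R) {
  x <- q * R
  (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# sphere pair-distance distribution on [0, 2R] (unnormalized)
oracle_sphere_pr <- function(r, R) {
  u <- r / R
  ifelse(r <= 2 * R, r^2 * (1 - 3 * u / 4 + u^3 / 16), 0)
}

# circular cylinder intensity by adaptive 1-D quadrature (independent of the
# package's fixed-order Gauss-Legendre path)
oracle_cylinder <- function(q, R, L) {
  vapply(q, function(qq) {
    f <- function(alpha) {
      u <- qq * R * sin(alpha)
      v <- qq * L * cos(alpha) / 2
      j <- ifelse(u < 1e-8, 1, 2 * besselJ(u, 1) / u)
      s <- ifelse(abs(v) < 1e-8, 1, sin(v) / v)
      (j * s)^2 * sin(alpha)
    }
    stats::integrate(f, 0, pi / 2, rel.tol = 1e-10)$value
  }, numeric(1))
}

# standard q grid for SAXS tests
q_default <- function(n = 220, lo = 0.008, hi = 0.4) seq(lo, hi, length.out = n)
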