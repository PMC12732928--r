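# indirect Fourier transform and Dmax selection

test_that("IFT on a noise-free sphere recovers the closed-form P(r) and Rg", {
  q <- q_default()
  p <- simulate_saxs("sphere", list(r = 30), q, frac_sd = 0)
  f <- ift(p, dmax = 60)
  pref <- oracle_sphere_pr(f$pr$r, 30)
  rms <- sqrt(mean((f$pr$p / max(f$pr$p) - pref / max(pref))^2))
  expect_lt(rms, 0.02)
  expect_equal(f$rg, 30 * sqrt(3 / 5), tolerance = 0.01)
  expect_equal(f$rg, 23.2, tolerance = 0.3 / 23.2)
  expect_equal(f$i0, 1, tolerance = 0.01)
  # endpoint zeros and non-negativity of a convex body
  expect_equal(f$pr$p[c(1, nrow(f$pr))], c(0, 0))
  expect_gte(min(f$pr$p), -0.01 * max(f$pr$p))
})

test_that("real-space Rg identity holds on the returned grid", {
  q <- q_default()
  p <- simulate_saxs("sphere", list(r = 30), q, frac_sd = 0)
  f <- ift(p, dmax = 60)
  r <- f$pr$r
  w <- c(diff(r)[1] / 2, (head(diff(r), -1) + tail(diff(r), -1)) / 2, diff(r)[1] / 2)
  rg2 <- sum(w * r^2 * f$pr$p) / (2 * sum(w * f$pr$p))
  expect_equal(f$rg, sqrt(rg2), tolerance = 1e-9)
})

test_that("IFT back-transform fits 2%-noise data with reduced chi^2 <= 1.5", {
  q <- q_default()
  p <- simulate_saxs("sphere", list(r = 30), q, frac_sd = 0.02, seed = 21)
  f <- ift(p, dmax = 60)
  expect_lte(f$chisq_red, 1.5)
  # and the reported chi^2 is reproducible from the returned P(r)
  pred <- f$fitted
  chisq <- sum(((p$I - pred) / p$sigma)^2)
  expect_equal(chisq / max(nrow(p) - f$n_effective, 1), f$chisq_red, tolerance = 1e-9)
})

test_that("IFT of the elliptical-cylinder default shape reproduces its closed-form Rg", {
  q <- seq(0.004, 0.35, length.out = 260)
  p <- simulate_saxs("elliptical_cylinder", list(a = 77, nu = 1.2, l = 16), q, frac_sd = 0)
  f <- ift(p, dmax = 190)
  expect_equal(f$rg, model_rg("elliptical_cylinder", list(a = 77, nu = 1.2, l = 16)),
               tolerance = 0.02)
})

test_that("Dmax scan selects the true support of a sphere", {
  q <- q_default()
  p <- simulate_saxs("sphere", list(r = 30), q, frac_sd = 0)
  sc <- scan_dmax(p, seq(40, 100, by = 10))
  expect_gte(sc$best_dmax, 55 - 5)
  expect_lte(sc$best_dmax, 70)
  # truncated-support candidates improve monotonically toward the truth
  sc2 <- scan_dmax(p, c(35, 40, 45, 50))
  expect_true(all(diff(sc2$scores$score) > 0))
  # single candidate is returned unchanged
  expect_equal(scan_dmax(p, 60)$best_dmax, 60)
})

test_that("undersized Dmax warns about the resolution limit", {
  q <- q_default(120, 0.05, 0.4)
  p <- simulate_saxs("sphere", list(r = 30), q, frac_sd = 0)
  expect_warning(ift(p, dmax = 5), "resolution")
})
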