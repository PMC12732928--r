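# Guinier, cross-section and Kratky reductions

test_that("Guinier fit inverts an ideal Guinier scatterer exactly", {
  q <- q_default(300, 0.004, 0.3)
  p <- simulate_saxs("guinier", list(rg = 60), q, frac_sd = 0)
  g <- guinier_fit(p)
  expect_equal(g$rg, 60, tolerance = 1e-6)
  expect_equal(g$i0, 1, tolerance = 1e-6)
  expect_lte(g$qrg_max, 1.3 + 1e-9)
})

test_that("Guinier fit on a sphere agrees with R*sqrt(3/5) within the window systematic", {
  q <- q_default(300, 0.004, 0.3)
  p <- simulate_saxs("sphere", list(r = 30), q, frac_sd = 0)
  g <- guinier_fit(p)
  # a finite qRg <= 1.3 window carries a known % -level systematic for spheres
  expect_equal(g$rg, 30 * sqrt(3 / 5), tolerance = 0.03)
})

test_that("increasing low-q intensity yields a no-Guinier-region error", {
  q <- q_default(50, 0.004, 0.1)
  p <- saxs_profile(q, 1 + 10 * q, sigma = rep(0.01, 50))
  expect_error(guinier_fit(p), "no Guinier region")
})

test_that("cross-sectional Guinier inverts a synthetic infinite rod", {
  q <- seq(0.02, 0.35, length.out = 150)
  I <- exp(-q^2 * 25 / 2) / q
  p <- saxs_profile(q, I, sigma = 0.01 * I)
  cs <- cross_section_guinier(p, q_window = c(0.02, 0.35))
  expect_equal(cs$rc, 5, tolerance = 1e-6)
  expect_equal(cs$diameter, 2 * 5 * sqrt(2), tolerance = 1e-6)
})

test_that("rod diameter formula matches the helix-scale arithmetic", {
  expect_equal(round(rod_diameter(4.86), 1), 13.7)
  expect_equal(rod_diameter(0.5), sqrt(2), tolerance = 1e-12)
})

test_that("flat intensity gives a no-rod-regime error", {
  q <- seq(0.02, 0.3, length.out = 60)
  p <- saxs_profile(q, rep(1, 60), sigma = rep(0.01, 60))
  expect_error(cross_section_guinier(p, q_window = c(0.02, 0.3)), "no rod-like regime")
})

test_that("dimensionless Kratky of an ideal Guinier scatterer peaks at (sqrt(3), 3/e)", {
  for (rg in c(20, 60, 150)) {
    q <- seq(0.002, 6 / rg, length.out = 400)
    p <- simulate_saxs("guinier", list(rg = rg), q, frac_sd = 0)
    k <- dimensionless_kratky(p, guinier_fit(p))
    expect_equal(attr(k, "peak_x"), sqrt(3), tolerance = 1e-3)
    expect_equal(attr(k, "peak_y"), 3 / exp(1), tolerance = 1e-3)
  }
})

test_that("Kratky transform is invariant to joint intensity rescaling", {
  q <- q_default(200, 0.004, 0.25)
  p1 <- simulate_saxs("guinier", list(rg = 60), q, frac_sd = 0)
  p2 <- simulate_saxs("guinier", list(rg = 60), q, i0 = 2, frac_sd = 0)
  k1 <- dimensionless_kratky(p1, guinier_fit(p1))
  k2 <- dimensionless_kratky(p2, guinier_fit(p2))
  expect_equal(k1$y, k2$y, tolerance = 1e-9)
})

test_that("flat profile reports no interior Kratky peak", {
  q <- q_default(100, 0.004, 0.2)
  p <- saxs_profile(q, rep(1, 100), sigma = rep(0.01, 100))
  g <- guinier_fit(simulate_saxs("guinier", list(rg = 60), q, frac_sd = 0))
  k <- dimensionless_kratky(p, g)
  expect_false(attr(k, "has_peak"))
  expect_true(all(diff(k$y) > 0))
})

test_that("model_rg closed forms and limits are exact", {
  expect_equal(model_rg("elliptical_cylinder", list(a = 77, nu = 1.2, l = 16)),
               sqrt((77^2 + 92.4^2) / 4 + 16^2 / 12), tolerance = 1e-12)
  expect_equal(round(model_rg("elliptical_cylinder", list(a = 77, nu = 1.2, l = 16)), 1), 60.3)
  expect_equal(model_rg("sphere", list(r = 30)), 30 * sqrt(3 / 5))
  # thin-disk limit: L -> 0 with a = b = R gives sqrt(R^2/2)
  expect_equal(model_rg("elliptical_cylinder", list(a = 50, nu = 1, l = 1e-9)),
               sqrt(50^2 / 2), tolerance = 1e-6)
  expect_error(model_rg("torus", list(r = 1)), "unknown model")
})

test_that("volume-to-MW conversion is linear with the documented divisor", {
  m <- volume_to_mw(105)
  expect_equal(m$mw_kda, 86.6, tolerance = 0.01)
  expect_equal(m$divisor_nm3_per_kda, 1.212, tolerance = 1e-3)
  expect_equal(volume_to_mw(1.212)$mw_kda, 1, tolerance = 1e-3)
  expect_equal(volume_to_mw(210)$mw_kda, 2 * volume_to_mw(105)$mw_kda)
})
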