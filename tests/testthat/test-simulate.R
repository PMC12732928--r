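# synthetic-data generators: closed-form agreement, determinism, conservation

test_that("noise-free SAXS simulation matches closed forms exactly", {
  q <- q_default(100, 0.005, 0.3)
  p <- simulate_saxs("guinier", list(rg = 60), q, frac_sd = 0)
  expect_equal(p$I, exp(-q^2 * 1200), tolerance = 1e-12)
  expect_true(all(p$sigma == 0))

  ps <- simulate_saxs("sphere", list(r = 30), q, frac_sd = 0)
  expect_lt(max(abs(ps$I - oracle_sphere(q, 30)) / oracle_sphere(q, 30)), 1e-10)
})

test_that("SAXS simulation is reproducible under a fixed seed", {
  q <- q_default(50)
  a <- simulate_saxs("sphere", list(r = 30), q, frac_sd = 0.02, seed = 99)
  b <- simulate_saxs("sphere", list(r = 30), q, frac_sd = 0.02, seed = 99)
  expect_identical(a, b)
  c <- simulate_saxs("sphere", list(r = 30), q, frac_sd = 0.02, seed = 100)
  expect_false(identical(a$I, c$I))
})

test_that("unknown SAXS model is a parameter error", {
  expect_error(simulate_saxs("torus", list(r = 1), q_default(20)), "unknown model")
})

test_that("MALDI peak positions follow the protonated n*M/z ladder", {
  pk <- simulate_maldi(17413.8, n = 2, z = 1, mass_error_ppm = 0)
  expect_equal(pk$mz, 2 * 17413.8 + 1.00728, tolerance = 1e-9)
  # (6M + 2p)/2 collapses onto (3M + p)/1
  pk2 <- simulate_maldi(17413.8, n = c(3, 6), z = 1:2, mass_error_ppm = 0)
  expect_equal(pk2$mz[pk2$n_true == 6 & pk2$z_true == 2],
               pk2$mz[pk2$n_true == 3 & pk2$z_true == 1])
  pk3 <- simulate_maldi(1000, n = 1, z = 1, mass_error_ppm = 0)
  expect_equal(pk3$mz, 1001.00728)
  # intensities decay with oligomer order
  pk4 <- simulate_maldi(17413.8, n = 2:7, z = 1, mass_error_ppm = 0)
  expect_true(all(diff(pk4$intensity[order(pk4$n_true)]) < 0))
})

test_that("AFM simulation renders caps of the specified height", {
  sim <- simulate_afm(1, a1_mean = 20, a1_sd = 1e-9, a2_mean = 10, a2_sd = 1e-9,
                      z_mean = 2, z_sd = 1e-9, background_sd = 0, seed = 1)
  # apex need not coincide with a pixel centre: sub-pixel sampling tolerance
  expect_equal(max(sim$map$heights), 2, tolerance = 5e-3)
  expect_equal(sim$truth$a1, 20, tolerance = 1e-6)
})

test_that("particle-free AFM control never crosses the 0.5 nm threshold", {
  sim <- simulate_afm(0, image_size = 256, background_sd = 0.05, seed = 4)
  expect_lt(max(sim$map$heights), 0.5)
})

test_that("AFM ground truth reproduces the class parameters at n = 1000", {
  cls <- afm_particle_classes()
  for (i in seq_len(nrow(cls))) {
    sim <- simulate_afm(1000, cls$a1_mean[i], cls$a1_sd[i], cls$a2_mean[i],
                        cls$a2_sd[i], cls$z_mean[i], cls$z_sd[i],
                        pixel_size = 2, background_sd = 0, seed = 1000 + i)
    sem <- cls$a1_sd[i] / sqrt(1000)
    expect_lt(abs(mean(sim$truth$a1) - cls$a1_mean[i]), 3 * sem + 0.05 * cls$a1_mean[i])
    expect_lt(abs(mean(sim$truth$z) - cls$z_mean[i]),
              3 * cls$z_sd[i] / sqrt(1000) + 0.05 * cls$z_mean[i])
    expect_true(all(sim$truth$a1 >= sim$truth$a2))
  }
})

test_that("ITC peaks integrate to their specified heats", {
  tg <- simulate_itc(heats = 10, noise_sd = 0, baseline_drift = 0)
  on <- tg$time_s >= 300
  got <- sum(diff(tg$time_s[on]) * (head(tg$power_uW[on], -1) + tail(tg$power_uW[on], -1)) / 2)
  expect_equal(got, 10, tolerance = 1e-3)

  # several non-overlapping peaks: total energy conserved within 0.5%
  heats <- c(-12, -9, -7, -5)
  tg2 <- simulate_itc(heats = heats, noise_sd = 0)
  total <- sum(integrate_injections(tg2)$heat_uJ)
  expect_equal(total, sum(heats), tolerance = 5e-3)
})

test_that("zero injections give a flat baseline and same-seed determinism holds", {
  tg <- simulate_itc(heats = numeric(0), noise_sd = 0)
  expect_true(all(tg$power_uW == 0))
  a <- simulate_itc(heats = -5, noise_sd = 0.02, seed = 3)
  b <- simulate_itc(heats = -5, noise_sd = 0.02, seed = 3)
  expect_identical(a$power_uW, b$power_uW)
})

test_that("temperature series preserves the programmed |heat| ordering", {
  temps <- c(15, 25, 37)
  mags <- c(300, 200, 100)  # uJ total, decreasing with temperature
  heats <- purrr::map2_dfr(temps, mags, function(Tc, Q) {
    tg <- simulate_itc(heats = rep(-Q / 20, 20), temperature = Tc,
                       noise_sd = 0.02, seed = Tc)
    integrate_injections(tg)
  })
  tr <- temperature_trend(heats)
  expect_true(tr$strict)
  expect_equal(tr$ordering, c(15, 25, 37))
})
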