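# ITC peak integration and temperature trend

test_that("a single known peak integrates to its heat", {
  tg <- simulate_itc(heats = 10, noise_sd = 0, baseline_drift = 0)
  h <- integrate_injections(tg)
  expect_equal(h$heat_uJ, 10, tolerance = 5e-3)
})

test_that("baseline removal cancels linear drift without injected heat", {
  tg <- simulate_itc(heats = rep(0, 6), baseline_drift = 0.01, noise_sd = 0)
  h <- integrate_injections(tg)
  expect_true(all(abs(h$heat_uJ) < 0.2))
})

test_that("integration is invariant to a constant power offset", {
  tg <- simulate_itc(heats = c(-10, -7), noise_sd = 0)
  shifted <- itc_thermogram(tg$time_s, tg$power_uW + 3.21,
                            attr(tg, "injections")$time_s,
                            temperature = attr(tg, "temperature"))
  expect_equal(integrate_injections(tg)$heat_uJ,
               integrate_injections(shifted)$heat_uJ, tolerance = 1e-9)
})

test_that("equal injections produce a flat isotherm", {
  # dissociation-scale injections (tens of uJ) at the default 0.02 uW noise
  tg <- simulate_itc(heats = rep(-50, 20), noise_sd = 0.02, seed = 12)
  h <- integrate_injections(tg)
  expect_equal(nrow(h), 20L)
  expect_lt(sd(h$heat_uJ), 0.02 * 50)
})

test_that("energy closure holds within 0.5% clean and 2% with drift + noise", {
  heats <- c(-60, -50, -40, -30, -20)
  clean <- simulate_itc(heats = heats, noise_sd = 0)
  expect_equal(sum(integrate_injections(clean)$heat_uJ), sum(heats),
               tolerance = 5e-3)
  messy <- simulate_itc(heats = heats, noise_sd = 0.02,
                        baseline_drift = 0.002, seed = 13)
  expect_equal(sum(integrate_injections(messy)$heat_uJ), sum(heats),
               tolerance = 0.02)
})

test_that("windows longer than the spacing and NaN power are rejected", {
  tg <- simulate_itc(heats = c(-5, -5), noise_sd = 0)
  expect_error(integrate_injections(tg, window = 400), "spacing")
  bad <- tg
  expect_error(itc_thermogram(c(0, 1, 2), c(0, NaN, 0), 1), "non-finite")
})

test_that("temperature trend verdicts: monotone, ties, too-few-temperatures", {
  h <- tibble::tibble(temperature = rep(c(15, 25, 37), each = 2),
                      heat_uJ = -c(150, 150, 100, 100, 50, 50))
  tr <- temperature_trend(h)
  expect_true(tr$strict)
  expect_equal(tr$ordering, c(15, 25, 37))

  tied <- tibble::tibble(temperature = c(15, 25), heat_uJ = c(-100, -100))
  tr2 <- temperature_trend(tied)
  expect_false(tr2$strict)
  expect_true(tr2$monotone)
  expect_length(tr2$ties, 2)

  expect_error(temperature_trend(tibble::tibble(temperature = 25, heat_uJ = -1)),
               ">= 2")
})
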