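# MALDI oligomer-series assignment

test_that("predict_mz follows the protonated ladder and its degeneracies", {
  M <- 17413.8
  expect_equal(predict_mz(M, 2, 1), 2 * M + 1.00728)
  expect_equal(predict_mz(M, 6, 2), predict_mz(M, 3, 1))
  expect_equal(predict_mz(1000, 1, 1), 1001.00728)
  expect_equal(predict_mz(1000, 1, 1, protonated = FALSE), 1000)
  # monotonicity: increasing in n at fixed z, decreasing in z at fixed n
  expect_true(all(diff(predict_mz(M, 1:8, 1)) > 0))
  expect_true(all(diff(predict_mz(M, 6, 1:3)) < 0))
})

test_that("monomer mass estimation inverts anchor peaks", {
  one <- estimate_monomer_mass(data.frame(mz = 1001.00728, n = 1, z = 1))
  expect_equal(one$mass, 1000, tolerance = 1e-9)
  expect_equal(one$sd, 0)

  dimer <- estimate_monomer_mass(data.frame(mz = 34828.6, n = 2, z = 1))
  expect_equal(dimer$mass, (34828.6 - 1.00728) / 2, tolerance = 1e-9)

  three <- estimate_monomer_mass(
    data.frame(mz = c(34828.6, 52245.1, 69653.1), n = 2:4, z = 1))
  expect_lt(abs(three$mass - 17414), 1)
  expect_gt(three$sd, 0)
})

test_that("noise-free simulated series is inverted exactly (sd = 0)", {
  pk <- simulate_maldi(17413.8, n = 2:5, z = 1, mass_error_ppm = 0)
  est <- estimate_monomer_mass(
    data.frame(mz = pk$mz, n = pk$n_true, z = pk$z_true))
  expect_equal(est$mass, 17413.8, tolerance = 1e-9)
  expect_lt(est$sd, 1e-9)
})

test_that("inconsistent anchors warn but do not fail", {
  expect_warning(
    estimate_monomer_mass(data.frame(mz = c(34828.6, 35100), n = c(2, 2), z = 1)),
    "inconsistent"
  )
})

test_that("peak assignment finds the trimer/hexamer charge degeneracy", {
  a <- assign_peaks(data.frame(mz = 52245.1), monomer_mass = 17414)
  expect_equal(a$n, 3L)
  expect_equal(a$z, 1L)
  expect_true(a$ambiguous)
  alt <- a$alternatives[[1]]
  expect_true(any(alt$n == 6 & alt$z == 2))
})

test_that("the dimer peak is assigned within 20 ppm and junk is unassigned", {
  a <- assign_peaks(data.frame(mz = 34828.6), monomer_mass = 17413.8)
  expect_equal(c(a$n, a$z), c(2L, 1L))
  expect_lt(abs(a$error_ppm), 20)

  junk <- assign_peaks(data.frame(mz = 0.5 * 17414 - 1000), 17414, tol_ppm = 100)
  expect_true(is.na(junk$n))
  expect_equal(junk$n_candidates, 0L)
})

test_that("round trip: every simulated (n, z) is recovered by assignment", {
  pk <- simulate_maldi(17413.8, n = 2:7, z = 1:2, mass_error_ppm = 0)
  asg <- assign_peaks(pk, 17413.8)
  for (i in seq_len(nrow(pk))) {
    cand <- rbind(asg[i, c("n", "z")], asg$alternatives[[i]][c("n", "z")])
    expect_true(any(cand$n == pk$n_true[i] & cand$z == pk$z_true[i]),
                info = sprintf("peak %d (n=%d z=%d)", i, pk$n_true[i], pk$z_true[i]))
  }
})

test_that("series report covers the full observed oligomer ladder", {
  peaks <- data.frame(mz = c(34828.6, 52245.1, 69653.1, 87145.6, 43573.6,
                             104609.9, 122061.4, 61003.6))
  sr <- series_report(assign_peaks(peaks, 17414, tol_ppm = 2000))
  expect_true(all(2:7 %in% sr$stoichiometries))
  expect_gte(sr$n_max, 7)
  expect_equal(sr$n_unassigned, 0L)

  empty <- series_report(assign_peaks(data.frame(mz = numeric()), 17414))
  expect_length(empty$stoichiometries, 0)

  # one peak, one assignment (z_max = 1 suppresses the charge degeneracies)
  one <- series_report(assign_peaks(data.frame(mz = 34828.6), 17414, z_max = 1))
  expect_equal(one$n_max, 2L)
})
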