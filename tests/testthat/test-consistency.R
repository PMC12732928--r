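# cross-technique stoichiometry and dimension reconciliation

test_that("stoichiometry ranking reproduces the tetramer/pentamer call", {
  for (mw in c(80, 82.5, 85)) {
    top <- head(stoichiometry_from_mw(mw, 17.5)$n, 2)
    expect_setequal(top, c(4, 5))
  }
  # exact multiples are exact
  s <- stoichiometry_from_mw(2 * 17.5, 17.5)
  expect_equal(s$n[1], 2L)
  expect_equal(s$residual[1], 0)
  # native-gel class III midpoint points at the tetramer
  expect_equal(stoichiometry_from_mw(67.5, 17.4)$n[1], 4L)
  # exact n*M recovery for all n
  for (n in 1:10) {
    expect_equal(stoichiometry_from_mw(n * 17.4, 17.4)$n[1], n)
  }
})

test_that("half-integer ratio ties break toward the smaller n", {
  s <- stoichiometry_from_mw(17.5 * 4.5, 17.5)
  expect_equal(s$n[1], 4L)
})

test_that("rod-versus-helix verdicts follow the tolerance band", {
  r <- rod_vs_helix(13.7)
  expect_equal(r$ratio, 13.7 / 12, tolerance = 1e-9)
  expect_true(r$consistent)
  expect_false(rod_vs_helix(24)$consistent)
  expect_equal(rod_vs_helix(12)$ratio, 1)
})

test_that("AFM-vs-SAXS dimension match reports the documented verdicts", {
  b <- afm_vs_saxs(14.2, 20.8)
  expect_equal(b$ratio, 28.4 / 20.8, tolerance = 1e-9)
  expect_equal(b$verdict, "borderline")
  expect_equal(afm_vs_saxs(10, 20)$verdict, "matching")
  expect_equal(afm_vs_saxs(50, 20)$verdict, "not matching")
})

test_that("report assembles partial evidence and rejects empty input", {
  maldi_only <- build_report(maldi = 17.414)
  expect_equal(maldi_only$monomer_kda, 17.414)
  expect_null(maldi_only$stoichiometry)
  expect_true("saxs" %in% maldi_only$missing_techniques)

  expect_error(build_report(), "no evidence")
})

test_that("default synthetic pipeline reproduces the {4, 5} stoichiometry call", {
  pk <- simulate_maldi(17413.8, n = 2:7, z = 1:2, mass_error_ppm = 50, seed = 14)
  est <- estimate_monomer_mass(data.frame(mz = pk$mz, n = pk$n_true, z = pk$z_true))
  rep <- build_report(maldi = est, saxs = list(volume_nm3 = 105, rod_diameter = 13.7))
  expect_setequal(rep$top_stoichiometries, c(4, 5))
  expect_true(rep$helix_check$consistent)
})

test_that("report generation is pure (identical inputs, identical JSON)", {
  rep <- build_report(maldi = 17.414, saxs = list(volume_nm3 = 105))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_report_json(rep, f1)
  write_report_json(build_report(maldi = 17.414, saxs = list(volume_nm3 = 105)), f2)
  expect_identical(readLines(f1), readLines(f2))
})
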