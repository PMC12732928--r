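# AFM morphometry: flattening, detection, ellipse measurement, classes

test_that("flattening removes a tilted plane to numerical precision", {
  plane <- outer(seq_len(64), seq_len(64), function(i, j) 0.02 * j + 0.5)
  m <- afm_heightmap(plane, 1)
  flat <- afm_flatten(m)
  expect_lt(max(abs(flat$heights)), 1e-9)
  # order 0 on an already flat map leaves zero residual too
  flat0 <- afm_flatten(afm_heightmap(matrix(1, 32, 32), 1), order = 0)
  expect_lt(max(abs(flat0$heights)), 1e-12)
})

test_that("flattening preserves particle height on a tilted background", {
  sim <- simulate_afm(1, a1_mean = 15, a1_sd = 1e-9, a2_mean = 8, a2_sd = 1e-9,
                      z_mean = 2, z_sd = 1e-9, background_sd = 0, seed = 5)
  tilted <- sim$map$heights +
    outer(seq_len(nrow(sim$map$heights)), seq_len(ncol(sim$map$heights)),
          function(i, j) 0.005 * j)
  flat <- afm_flatten(afm_heightmap(tilted, sim$map$pixel_size))
  expect_equal(max(flat$heights), 2, tolerance = 0.02)
})

test_that("detection finds separated caps and ignores pure background", {
  sim <- simulate_afm(2, a1_mean = 12, a1_sd = 0.5, a2_mean = 8, a2_sd = 0.5,
                      z_mean = 2, z_sd = 0.1, background_sd = 0.05, seed = 6)
  det <- detect_particles(sim$map)
  expect_equal(det$n_particles, 2L)

  ctl <- simulate_afm(0, image_size = 256, background_sd = 0.05, seed = 7)
  expect_equal(detect_particles(ctl$map)$n_particles, 0L)
})

test_that("particle-free control stays clean across 20 seeds", {
  for (s in 1:20) {
    ctl <- simulate_afm(0, image_size = 128, background_sd = 0.05, seed = s)
    expect_equal(detect_particles(ctl$map)$n_particles, 0L)
  }
})

test_that("moment-based ellipse recovers ideal filled-ellipse axes", {
  # binary ellipse mask, no height shape: build directly at 1 nm/px
  n <- 101
  xx <- outer(seq_len(n) - 51, rep(1, n))
  yy <- t(xx)
  mask <- (xx / 20)^2 + (yy / 10)^2 <= 1
  m <- afm_heightmap(mask * 1.0, 1)
  det <- detect_particles(m, threshold = 0.5, boundary_threshold = 0.5)
  rec <- measure_particles(det)
  expect_equal(rec$a1, 20, tolerance = 0.5 / 20)
  expect_equal(rec$a2, 10, tolerance = 0.5 / 10)
  expect_equal(rec$ratio, 2, tolerance = 0.05)

  circ <- (xx / 15)^2 + (yy / 15)^2 <= 1
  det2 <- detect_particles(afm_heightmap(circ * 1.0, 1), boundary_threshold = 0.5)
  rec2 <- measure_particles(det2)
  expect_lte(rec2$ratio, 1.05)
})

test_that("a rendered class-III particle is measured within 10%", {
  sim <- simulate_afm(1, a1_mean = 32.8, a1_sd = 1e-9, a2_mean = 20.5,
                      a2_sd = 1e-9, z_mean = 2.43, z_sd = 1e-9,
                      background_sd = 0.05, pixel_size = 1, seed = 8)
  rec <- measure_particles(detect_particles(sim$map))
  expect_equal(rec$a1, 32.8, tolerance = 0.10)
  expect_equal(rec$a2, 20.5, tolerance = 0.10)
  expect_equal(rec$z, 2.43, tolerance = 0.10)
  expect_true(rec$a1 >= rec$a2)
})

test_that("class segmentation honours the overlapping I/II windows", {
  parts <- tibble::tibble(a1 = c(18, 50, 70, 10))
  seg <- segment_ranges(parts)
  expect_setequal(seg$range[seg$a1 == 18], c("I", "II"))
  expect_true(all(seg$multi_range[seg$a1 == 18]))
  expect_equal(seg$range[seg$a1 == 50], "IV")
  expect_equal(seg$range[seg$a1 == 70], "unbinned")
  expect_equal(seg$range[seg$a1 == 10], "I")
})

test_that("Gaussian class statistics flag degenerate and undersized classes", {
  parts <- tibble::tibble(a1 = c(rep(30, 25), rep(50, 5)),
                          z = c(rep(2, 25), rep(1.9, 5)))
  seg <- segment_ranges(parts)
  expect_warning(st <- fit_range_gaussians(seg, params = c("a1", "z"), min_count = 20),
                 "fewer than")
  expect_false("IV" %in% st$range)  # only 5 particles there
  expect_true(all(st$degenerate[st$param == "a1"]))  # constant value
})

test_that("measured a1 >= a2 with ratio support >= 1 on a mixed field", {
  sim <- simulate_afm(40, a1_mean = 20, a1_sd = 6, a2_mean = 14, a2_sd = 5,
                      z_mean = 2, z_sd = 0.4, pixel_size = 1, seed = 9)
  rec <- measure_particles(detect_particles(afm_flatten(sim$map)))
  expect_gt(nrow(rec), 30)
  expect_true(all(rec$a1 >= rec$a2))
  expect_true(all(rec$ratio >= 1))
})
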