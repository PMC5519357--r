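test_that("spec validation rejects unphysical parameters", {
  expect_error(membrane_spec(area_modulus = 0), "positive")
  expect_error(membrane_spec(area_modulus = -10), "positive")
  expect_error(membrane_spec(area0 = 0), "area0")
  expect_error(membrane_spec(temperature = -1), "temperature")
  expect_error(membrane_spec(rho = 1), "rho")
  expect_error(membrane_spec(rho = -0.1), "rho")
  expect_error(membrane_spec(peak_sigma = 4, thickness = 3.8), "peak_sigma")
  expect_error(membrane_spec(n_phosphorus = 1), "n_phosphorus")
})

test_that("area series has the stationary variance the modulus implies", {
  # direct evaluation of kB*T*A0/K_A with an independent hand conversion
  target <- kB_ref * 303.15 * 130 / 240 * 1e21
  expect_equal(target, 2.267, tolerance = 1e-3)
  expect_equal(area_variance_nm4(240, 130, 303.15), target,
               tolerance = 1e-12)

  # stationary moments over many seeds
  vars <- vapply(1:50, function(sd) {
    var(generate_area_series(membrane_spec(n_frames = 20000, seed = sd))$areas)
  }, 0)
  expect_lt(abs(mean(vars) / target - 1), 0.02)
  means <- vapply(1:10, function(sd) {
    mean(generate_area_series(membrane_spec(n_frames = 20000, seed = sd))$areas)
  }, 0)
  expect_lt(abs(mean(means) - 130), 0.05)
})

test_that("same spec and seed give bit-identical output", {
  spec <- membrane_spec(n_frames = 500, seed = 11)
  expect_identical(generate_area_series(spec)$areas,
                   generate_area_series(spec)$areas)
  expect_identical(generate_phosphorus_z(spec, n_frames = 3),
                   generate_phosphorus_z(spec, n_frames = 3))
})

test_that("extending n_frames preserves earlier frames exactly", {
  a_short <- generate_area_series(membrane_spec(n_frames = 200, seed = 4,
                                                rho = 0.5))$areas
  a_long <- generate_area_series(membrane_spec(n_frames = 400, seed = 4,
                                               rho = 0.5))$areas
  expect_identical(a_short, a_long[1:200])

  spec <- membrane_spec(seed = 4, n_phosphorus = 50)
  z_short <- generate_phosphorus_z(spec, n_frames = 5)
  z_long <- generate_phosphorus_z(spec, n_frames = 9)
  expect_identical(z_short$z, z_long$z[1:nrow(z_short)])
})

test_that("area and coordinate streams are independent", {
  spec <- membrane_spec(n_frames = 100, seed = 21, n_phosphorus = 20)
  a1 <- generate_area_series(spec)$areas
  invisible(generate_phosphorus_z(spec, n_frames = 2))
  a2 <- generate_area_series(spec)$areas
  expect_identical(a1, a2)
})

test_that("AR(1) series has the requested lag-1 autocorrelation", {
  for (rho in c(0.3, 0.9)) {
    x <- generate_area_series(membrane_spec(n_frames = 50000, rho = rho,
                                            seed = 8))$areas
    r1 <- cor(x[-1], x[-length(x)])
    expect_lt(abs(r1 - rho), 0.02)
    # stationary variance unchanged by correlation
    expect_lt(abs(var(x) / area_variance_nm4(240, 130, 303.15) - 1), 0.1)
  }
})

test_that("phosphorus z distribution is bimodal, symmetric and leaflet-balanced", {
  spec <- membrane_spec(thickness = 3.8, peak_sigma = 0.35,
                        n_phosphorus = 200, seed = 2)
  z <- generate_phosphorus_z(spec, n_frames = 500)$z
  # brute-force histogram modes near +/- 1.9 nm
  m <- ceiling(max(abs(z)) / 0.1)
  h <- tabulate(pmin(floor(z / 0.1) + m + 1, 2 * m), nbins = 2 * m)
  mids <- (seq(-m, m - 1) + 0.5) * 0.1
  expect_lt(abs(mids[mids < 0][which.max(h[mids < 0])] + 1.9), 0.1)
  expect_lt(abs(mids[mids > 0][which.max(h[mids > 0])] - 1.9), 0.1)
  # mean within 3 standard errors of 0
  expect_lt(abs(mean(z)), 3 * sd(z) / sqrt(length(z)))
  # leaflet membership is balanced
  frac_up <- mean(z > 0)
  expect_lt(abs(frac_up - 0.5), 3 * sqrt(0.25 / length(z)))
})

test_that("zero peak width collapses to exact point masses", {
  spec <- membrane_spec(thickness = 3.0, peak_sigma = 0, n_phosphorus = 40,
                        seed = 6)
  z <- generate_phosphorus_z(spec, n_frames = 10)$z
  expect_true(all(z %in% c(-1.5, 1.5)))
})

test_that("generator output rejects invalid frame counts", {
  spec <- membrane_spec(seed = 1)
  expect_error(generate_phosphorus_z(spec, n_frames = 0), "positive")
})
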