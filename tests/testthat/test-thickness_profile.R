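test_that("density integrates to the per-frame atom count", {
  for (sd_ in 1:5) {
    spec <- membrane_spec(n_phosphorus = 50, seed = sd_,
                          thickness = 3 + 0.3 * sd_)
    z <- generate_phosphorus_z(spec, n_frames = 40)
    prof <- build_density_profile(z, bin_width = 0.07)
    expect_equal(sum(prof$density * prof$bin_width), prof$n_atoms,
                 tolerance = 1e-9)
    expect_true(all(diff(prof$bin_edges) > 0))
    expect_equal(max(abs(diff(diff(prof$bin_edges)))), 0, tolerance = 1e-12)
  }
})

test_that("profile of a bimodal generator shows two peaks straddling zero", {
  spec <- membrane_spec(thickness = 3.8, peak_sigma = 0.35,
                        n_phosphorus = 200, seed = 1)
  z <- generate_phosphorus_z(spec, n_frames = 1000)
  prof <- build_density_profile(z, bin_width = 0.05)
  th <- peak_to_peak_thickness(prof)
  expect_lt(th$peak_neg, 0)
  expect_gt(th$peak_pos, 0)
  # agreement with the no-interpolation argmax oracle within one bin
  expect_lt(abs(th$thickness - oracle_thickness(z$z, 0.05)), 0.05)
})

test_that("point masses land in exactly two bins and give d* exactly", {
  z <- data.frame(frame = 1L, atom = 1:2, z = c(-1.0, 1.0))
  prof <- build_density_profile(z, bin_width = 0.1, center = "none")
  expect_equal(sum(prof$density > 0), 2L)
  occupied <- prof$bin_mids[prof$density > 0]
  expect_lt(max(abs(abs(occupied) - 1.0)), 0.1)

  spec <- membrane_spec(thickness = 3.0, peak_sigma = 0, n_phosphorus = 40,
                        seed = 3)
  zt <- generate_phosphorus_z(spec, n_frames = 5)
  th <- peak_to_peak_thickness(build_density_profile(zt, bin_width = 0.05))
  expect_lt(abs(th$thickness - 3.0), 0.05)
})

test_that("profile is invariant under translation and reflection of z", {
  spec <- membrane_spec(n_phosphorus = 100, seed = 9)
  z <- generate_phosphorus_z(spec, n_frames = 200)
  prof <- build_density_profile(z, bin_width = 0.05)
  z_shift <- transform(z, z = z + 5)
  prof_shift <- build_density_profile(z_shift, bin_width = 0.05)
  expect_equal(prof_shift$density, prof$density)
  d0 <- peak_to_peak_thickness(prof)$thickness
  z_flip <- transform(z, z = -z)
  d_flip <- peak_to_peak_thickness(
    build_density_profile(z_flip, bin_width = 0.05))$thickness
  expect_equal(d_flip, d0, tolerance = 1e-12)
})

test_that("thickness is stable under bin halving", {
  spec <- membrane_spec(n_phosphorus = 200, seed = 12)
  z <- generate_phosphorus_z(spec, n_frames = 1000)
  d_coarse <- peak_to_peak_thickness(
    build_density_profile(z, bin_width = 0.1))$thickness
  d_fine <- peak_to_peak_thickness(
    build_density_profile(z, bin_width = 0.05))$thickness
  expect_lt(abs(d_coarse - d_fine), 0.1)
})

test_that("recovered thickness increases with the generator's d*", {
  d_grid <- c(3.0, 3.4, 3.8, 4.2)
  d_hat <- vapply(d_grid, function(d_) {
    spec <- membrane_spec(thickness = d_, peak_sigma = 0.35,
                          n_phosphorus = 200, seed = 17)
    z <- generate_phosphorus_z(spec, n_frames = 500)
    peak_to_peak_thickness(build_density_profile(z, 0.05))$thickness
  }, 0)
  expect_true(all(diff(d_hat) > 0))
  expect_lt(max(abs(d_hat - d_grid)), 0.1)
})

test_that("degenerate and monomodal inputs are rejected", {
  flat <- data.frame(frame = 1L, atom = 1:5, z = rep(2, 5))
  expect_error(build_density_profile(flat, 0.05, center = "none"),
               "identical")
  set.seed(2)
  mono <- data.frame(frame = 1L, atom = 1:5000, z = rnorm(5000, 0, 0.5))
  prof <- build_density_profile(mono, 0.1)
  expect_error(peak_to_peak_thickness(prof), "undefined")
  expect_error(build_density_profile(mono, -0.1), "bin_width")
  one <- data.frame(frame = 1L, atom = 1L, z = 1)
  expect_error(build_density_profile(one, 0.1), "at least 2")
})
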