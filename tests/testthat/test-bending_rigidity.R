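test_that("the polymer-brush relation reproduces the hand-computed example", {
  # K_A (d - d0)^2 / 24 at 240 mN/m, d = 4 nm, d0 = 1 nm:
  # 0.240 J/m2 * (3e-9 m)^2 / 24 = 9.0e-20 J; / kBT(303.15 K) = 21.50
  r <- compute_bending_rigidity(240, 4.0, temperature = 303.15)
  expect_equal(r$kappa_J, 9.0e-20, tolerance = 1e-12)
  expect_equal(r$kappa_kBT, 9.0e-20 / (kB_ref * 303.15), tolerance = 1e-12)
  expect_equal(r$kappa_kBT, 21.5, tolerance = 2e-4)
  # d = d0 gives exactly zero
  expect_identical(compute_bending_rigidity(240, 1.0,
                                            temperature = 303.15)$kappa_J, 0)
  # d0 defaults to 1 nm
  r2 <- compute_bending_rigidity(240, 4.0, d0 = 1.0, temperature = 303.15)
  expect_identical(r$kappa_J, r2$kappa_J)
})

test_that("stored kBT and joule values are mutually consistent", {
  r <- compute_bending_rigidity(183.7, 3.62, temperature = 343.15,
                                area_modulus_se = 4.1, thickness_se = 0.04)
  expect_equal(r$kappa_kBT * kB_ref * r$temperature, r$kappa_J,
               tolerance = 1e-12)
  expect_equal(r$kappa_se_kBT * kB_ref * r$temperature, r$kappa_se_J,
               tolerance = 1e-12)
  # unit round trip mN/m*nm2 -> J -> kBT -> J
  kap <- kappa_kBT_to_joules(kappa_joules_to_kBT(r$kappa_J, 343.15), 343.15)
  expect_equal(kap, r$kappa_J, tolerance = 1e-12)
})

test_that("kappa is monotone in K_A and in thickness", {
  ka_grid <- seq(150, 350, by = 50)
  k1 <- vapply(ka_grid, function(k)
    compute_bending_rigidity(k, 3.8, temperature = 303.15)$kappa_kBT, 0)
  expect_true(all(diff(k1) > 0))
  d_grid <- seq(3.0, 4.4, by = 0.2)
  k2 <- vapply(d_grid, function(d)
    compute_bending_rigidity(240, d, temperature = 303.15)$kappa_kBT, 0)
  expect_true(all(diff(k2) > 0))
})

test_that("unphysical inputs are reported, not clamped", {
  expect_error(compute_bending_rigidity(240, 0.8, temperature = 303.15),
               "unphysical")
  expect_error(compute_bending_rigidity(-5, 3.8, temperature = 303.15),
               "positive")
  expect_error(compute_bending_rigidity(240, 3.8), "temperature")
})

test_that("SE propagation follows first-order combination of both inputs", {
  r <- compute_bending_rigidity(240, 4.0, temperature = 303.15,
                                area_modulus_se = 12, thickness_se = 0.05)
  rel <- sqrt((12 / 240)^2 + (2 * 0.05 / 3)^2)
  expect_equal(r$kappa_se_J, r$kappa_J * rel, tolerance = 1e-12)
})

make_result <- function(label, kappa_kBT, se = 0.3, temperature = 303.15) {
  # invert the relation to get a K_A giving the desired kappa at d = 3.8
  d <- 3.8
  ka <- kappa_kBT * kB_ref * temperature * 24 / ((d - 1) * 1e-9)^2 / 1e-3
  rel <- se / kappa_kBT
  compute_bending_rigidity(ka, d, temperature = temperature,
                           area_modulus_se = rel * ka, label = label)
}

test_that("comparative report orders lipids and issues SE-aware verdicts", {
  res <- list(make_result("DOPC", 20), make_result("DAPC", 16),
              make_result("DDPC", 12))
  rep <- comparative_report(res)
  expect_identical(rep$table$label, c("DDPC", "DAPC", "DOPC"))
  expect_identical(pair_verdict(rep, "DDPC", "DOPC"), "lower")
  expect_identical(pair_verdict(rep, "DDPC", "DAPC"), "lower")
  expect_identical(pair_verdict(rep, "DOPC", "DDPC"), "higher")
  expect_identical(pair_verdict(rep, "DOPC", "DOPC"), "indistinguishable")
  expect_identical(rep$spread$lowest_label, "DDPC")
  expect_equal(rep$spread$spread_kBT, 8, tolerance = 1e-9)
})

test_that("widening every SE can only push verdicts to indistinguishable", {
  res_tight <- list(make_result("A", 15, se = 0.3),
                    make_result("B", 15.8, se = 0.3),
                    make_result("C", 18, se = 0.3))
  res_wide <- list(make_result("A", 15, se = 3),
                   make_result("B", 15.8, se = 3),
                   make_result("C", 18, se = 3))
  vt <- comparative_report(res_tight)$verdicts
  vw <- comparative_report(res_wide)$verdicts
  for (i in seq_len(nrow(vt))) {
    if (vw$verdict[i] != "indistinguishable") {
      expect_identical(vw$verdict[i], vt$verdict[i])
    }
  }
  expect_true(sum(vw$verdict == "indistinguishable") >=
                sum(vt$verdict == "indistinguishable"))
})

test_that("temperature groups must be comparable", {
  res <- list(make_result("DOPC", 20, temperature = 303.15),
              make_result("DAPC", 16, temperature = 323.15))
  expect_error(comparative_report(res), "at least 2 results")
  res3 <- list(make_result("DOPC", 20), make_result("DAPC", 16),
               make_result("DOPC", 19, temperature = 323.15),
               make_result("DAPC", 15.5, temperature = 323.15))
  rep <- comparative_report(res3)
  expect_identical(pair_verdict(rep, "DAPC", "DOPC", temperature = 323.15),
                   "lower")
  expect_error(pair_verdict(rep, "DAPC", "DOPC"), "temperature")
})

test_that("end-to-end synthetic pipeline recovers the true kappa", {
  hits <- 0L
  n_runs <- 20L
  for (sd_ in seq_len(n_runs)) {
    spec <- membrane_spec(area_modulus = 240, area0 = 130,
                          temperature = 303.15, n_frames = 8000,
                          thickness = 3.8, peak_sigma = 0.35,
                          n_phosphorus = 200, seed = 4000 + sd_)
    ka <- estimate_area_modulus(
      apply_equilibration_cut(generate_area_series(spec), 0.25))
    th <- peak_to_peak_thickness(
      build_density_profile(generate_phosphorus_z(spec, n_frames = 500),
                            0.05))
    r <- compute_bending_rigidity(ka, th, temperature = 303.15)
    kappa_true <- 240e-3 * ((3.8 - 1) * 1e-9)^2 / 24
    if (abs(r$kappa_J - kappa_true) <= 3 * r$kappa_se_J) hits <- hits + 1L
  }
  expect_gte(hits, round(0.95 * n_runs) - 1L)
})
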