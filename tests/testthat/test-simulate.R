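test_that("generators are deterministic for identical seed and parameters", {
  n <- noise_spec("gaussian", 0.02, seed = 77)
  expect_identical(sim_emission_spectrum(noise = n),
                   sim_emission_spectrum(noise = n))
  expect_identical(sim_drug_absorbance(0.5, noise = n),
                   sim_drug_absorbance(0.5, noise = n))
  expect_identical(sim_quench_titration("stern_volmer", list(K_SV = 4837, I0 = 1),
                                        seq(0, 5e-5, 1e-5), noise = n),
                   sim_quench_titration("stern_volmer", list(K_SV = 4837, I0 = 1),
                                        seq(0, 5e-5, 1e-5), noise = n))
  expect_identical(sim_partition_titration(159, noise = n),
                   sim_partition_titration(159, noise = n))
  expect_identical(sim_anisotropy_series(noise = n), sim_anisotropy_series(noise = n))
  expect_identical(sim_decay_series(0.385, noise = n),
                   sim_decay_series(0.385, noise = n))
  # different seeds give different data
  n2 <- noise_spec("gaussian", 0.02, seed = 78)
  expect_false(identical(sim_decay_series(0.385, noise = n),
                         sim_decay_series(0.385, noise = n2)))
})

test_that("generator noise does not disturb the global RNG stream", {
  withr::with_seed(5, {
    before <- runif(1)
  })
  withr::with_seed(5, {
    invisible(sim_decay_series(0.385, noise = noise_spec("gaussian", 0.1, seed = 3)))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("emission spectrum peaks at the requested wavelength", {
  s <- sim_emission_spectrum()
  expect_equal(s$wavelength_nm[which.max(s$value)], 334)
  zero <- sim_emission_spectrum(amplitude = 0)
  expect_true(all(zero$value == 0))
})

test_that("drug absorbance spectrum shows the hydrolytic band conversion", {
  intact <- sim_drug_absorbance(0)
  expect_equal(intact$wavelength_nm[which.max(intact$value)], 329)
  # minor band: local maximum near 258 nm
  lo <- intact[intact$wavelength_nm < 290, ]
  expect_equal(lo$wavelength_nm[which.max(lo$value)], 258)
  degraded <- sim_drug_absorbance(1)
  expect_equal(degraded$wavelength_nm[which.max(degraded$value)], 265)
  expect_error(sim_drug_absorbance(1.2), class = "spectrobind_invalid_parameter")
})

test_that("noiseless generators are exactly inverted by their paired fits", {
  sv <- sim_quench_titration("stern_volmer", list(K_SV = 4837, I0 = 1),
                             seq(0, 55e-6, length.out = 12))
  expect_rel_equal(suppressWarnings(fit_stern_volmer(sv))$K_SV, 4837, 1e-6)

  iso <- sim_quench_titration("isotherm", list(K_a = 5103, I0 = 1, Ic = 0.1),
                              seq(0, 6e-4, length.out = 12))
  fit <- fit_binding_isotherm(iso)
  expect_rel_equal(fit$K_a, 5103, 1e-6)
  expect_rel_equal(fit$Ic, 0.1, 1e-5)

  part <- sim_partition_titration(159, delta_A_max = 0.05)
  expect_rel_equal(fit_partition(part, "fixed_bound", delta_A_max = 0.05)$K_p,
                   159, 1e-6)

  an <- sim_anisotropy_series(T_grid = seq(10, 37, length.out = 16))
  expect_rel_equal(fit_thermotropic_transition(anisotropy_curve(an))$T_m, 23, 1e-6)

  dec <- sim_decay_series(0.385, t_grid = seq(0, 10, length.out = 12))
  expect_rel_equal(fit_first_order_decay(dec)$k, 0.385, 1e-6)
})

test_that("isotherm generator with Ic = I0 yields constant intensities", {
  t <- sim_quench_titration("isotherm", list(K_a = 5000, I0 = 1, Ic = 1),
                            seq(0, 5e-4, length.out = 6))
  expect_true(all(t$intensity == 1))
})

test_that("anisotropy generator hits the stated plateaus at the default G", {
  readings <- sim_anisotropy_series(T_grid = c(15, 37))
  curve <- anisotropy_curve(readings)
  expect_equal(curve$r[1], 0.339, tolerance = 1e-3)
  expect_equal(curve$r[2], 0.092, tolerance = 1e-3)
  flat <- sim_anisotropy_series(r_low = 0.2, r_high = 0.2)
  expect_equal(unique(round(anisotropy_curve(flat)$r, 12)), 0.2)
})

test_that("decay generator honours half-life algebra", {
  t_half <- log(2) / 0.385
  s <- sim_decay_series(0.385, A0 = 1, A_inf = 0, t_grid = c(0, t_half, 4))
  expect_equal(s$signal[2], 0.5, tolerance = 1e-9)
  const <- sim_decay_series(0, t_grid = c(0, 1, 2))
  expect_true(all(const$signal == 1))
})

test_that("noise spec validates its arguments", {
  expect_error(noise_spec("gaussian", 0.1), class = "spectrobind_invalid_parameter")
  expect_error(noise_spec("gaussian", -0.1, 1), class = "spectrobind_invalid_parameter")
  expect_silent(noise_spec("none"))
})
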