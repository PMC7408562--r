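test_that("Stern-Volmer fit recovers the generating constant from noiseless data", {
  conc <- seq(0, 55e-6, by = 5e-6)
  t <- sim_quench_titration("stern_volmer", list(K_SV = 4837, I0 = 1),
                            conc_grid = conc)
  fit <- suppressWarnings(fit_stern_volmer(t))
  expect_rel_equal(fit$K_SV, 4837, 1e-6)
  expect_equal(fit$intercept, 1, tolerance = 1e-6)
  expect_false(fit$non_quenching)
})

test_that("Stern-Volmer fit recovers any K_SV in [1e2, 1e5] from noiseless data", {
  for (ksv in c(1e2, 1e3, 4837, 1e4, 1e5)) {
    conc <- seq(0, 2 / ksv, length.out = 8)
    t <- sim_quench_titration("stern_volmer", list(K_SV = ksv, I0 = 5),
                              conc_grid = conc)
    fit <- suppressWarnings(fit_stern_volmer(t))
    expect_rel_equal(fit$K_SV, ksv, 1e-6)
  }
})

test_that("flat intensities give zero slope; rising intensities are flagged", {
  t <- quench_titration(seq(0, 50e-6, 10e-6), rep(2, 6))
  fit <- suppressWarnings(fit_stern_volmer(t))
  expect_equal(fit$K_SV, 0)
  t2 <- quench_titration(seq(0, 50e-6, 10e-6), c(1, 1.1, 1.2, 1.3, 1.4, 1.5))
  expect_true(fit_stern_volmer(t2)$non_quenching)
  expect_error(fit_stern_volmer(quench_titration(c(0, 1e-5), c(1, 0.9))),
               class = "spectrobind_invalid_input")
})

test_that("Stern-Volmer slope is recovered within 2% under 1% noise", {
  slopes <- vapply(1:60, function(i) {
    t <- sim_quench_titration("stern_volmer", list(K_SV = 4837, I0 = 1),
                              conc_grid = seq(0, 55e-6, length.out = 12),
                              noise = noise_spec("gaussian", 0.01, seed = 1000 + i))
    fit_stern_volmer(t)$K_SV
  }, numeric(1))
  expect_rel_equal(mean(slopes), 4837, 0.02)
})

test_that("bimolecular rate constant and classification match the static-quenching diagnosis", {
  kq <- bimolecular_rate_constant(5248, 6.4e-9)
  expect_rel_equal(kq, 8.2e11, 0.01)
  expect_equal(classify_quenching(kq), "static")
  # AGP: the arithmetic value of K_SV / tau0
  expect_rel_equal(bimolecular_rate_constant(3093, 6.4e-9), 4.83e11, 0.01)
  expect_equal(bimolecular_rate_constant(0), 0)
  expect_equal(classify_quenching(1e9), "dynamic-compatible")
  expect_equal(classify_quenching(2.0e10), "dynamic-compatible")  # strict inequality
  expect_error(bimolecular_rate_constant(5000, 0), class = "spectrobind_invalid_parameter")
})

test_that("binding isotherm refits its own noiseless forward model", {
  conc <- seq(0, 4e-4, length.out = 12)
  t <- sim_quench_titration("isotherm", list(K_a = 5103, I0 = 1, Ic = 0),
                            conc_grid = conc)
  fit <- fit_binding_isotherm(t)
  expect_rel_equal(fit$K_a, 5103, 1e-6)
  expect_lt(fit$Ic, 1e-6)
  expect_rel_equal(fit$K_d, 1 / 5103, 1e-6)
})

test_that("isotherm recovery holds across K_a and residual-fluorescence ranges", {
  for (ka in c(1e2, 1e3, 1e4, 1e5)) {
    for (icfrac in c(0, 0.3, 0.5)) {
      t <- sim_quench_titration("isotherm",
                                list(K_a = ka, I0 = 2, Ic = 2 * icfrac),
                                conc_grid = seq(0, 3 / ka, length.out = 10))
      fit <- fit_binding_isotherm(t)
      expect_rel_equal(fit$K_a, ka, 1e-5)
      expect_equal(fit$Ic, 2 * icfrac, tolerance = 2 * 1e-5 + 1e-8)
    }
  }
})

test_that("half-saturation point gives half the quenching amplitude", {
  ka <- 5103
  t <- sim_quench_titration("isotherm", list(K_a = ka, I0 = 1, Ic = 0.2),
                            conc_grid = c(0, 1 / ka))
  dI <- 1 - t$intensity[t$conc_M > 0]
  expect_equal(dI, (1 - 0.2) / 2, tolerance = 1e-12)
})

test_that("median K_a bias is below 2% under 1% intensity noise", {
  kas <- vapply(1:60, function(i) {
    t <- sim_quench_titration("isotherm", list(K_a = 5103, I0 = 1, Ic = 0),
                              conc_grid = seq(0, 2 / 5103, length.out = 12),
                              noise = noise_spec("gaussian", 0.01, seed = 2000 + i))
    fit_binding_isotherm(t)$K_a
  }, numeric(1))
  expect_rel_equal(median(kas), 5103, 0.02)
})

test_that("dissociation constant inverts the association constant", {
  expect_rel_equal(dissociation_constant(5103), 1.96e-4, 0.01)
  expect_rel_equal(dissociation_constant(4016), 2.49e-4, 0.01)
  expect_equal(dissociation_constant(1000), 1e-3)
  expect_error(dissociation_constant(0), class = "spectrobind_invalid_parameter")
  k <- c(100, 1000, 10000)
  expect_true(all(diff(dissociation_constant(k)) < 0))
})

test_that("Gibbs free energy matches the reported binding energies", {
  expect_rel_equal(gibbs_free_energy(4016, 298.15), -2.06e4, 0.005)
  expect_rel_equal(gibbs_free_energy(8184, 298.15), -2.23e4, 0.005)
  expect_equal(gibbs_free_energy(1, 298.15), 0)
  expect_true(all(diff(gibbs_free_energy(c(10, 100, 1000))) < 0))
  expect_error(gibbs_free_energy(-1), class = "spectrobind_invalid_parameter")
  expect_error(gibbs_free_energy(100, 0), class = "spectrobind_invalid_parameter")
})

test_that("van't Hoff two-point form matches the closed-form oracle", {
  th <- vant_hoff(c(2000, 4000), c(288.15, 298.15))
  expect_rel_equal(th$dH, 4.95e4, 0.005)
  expect_equal(th$dG, th$dH - th$T * th$dS, tolerance = 1e-6)
  # temperature-independent K: dH = 0, dS = R ln K
  th0 <- vant_hoff(c(3000, 3000), c(288.15, 298.15))
  expect_equal(th0$dH, 0, tolerance = 1e-8)
  expect_equal(th0$dS, 8.3145 * log(3000), tolerance = 1e-6)
  expect_error(vant_hoff(c(1000, 2000), c(298.15, 298.15)),
               class = "spectrobind_invalid_input")
})

test_that("van't Hoff regression path agrees with the closed form on exact data", {
  dH <- 3e4
  dS <- 120
  Ts <- c(283.15, 293.15, 303.15, 313.15)
  K <- exp(-dH / (8.3145 * Ts) + dS / 8.3145)
  th <- vant_hoff(K, Ts)
  expect_rel_equal(th$dH, dH, 1e-8)
  expect_rel_equal(th$dS, dS, 1e-8)
  expect_equal(th$dG, th$dH - th$T * th$dS, tolerance = 1e-6)
})

test_that("titration files round-trip with temperature metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# temperature_C: 15", "conc_M,intensity",
               "0,1.0", "1e-05,0.95", "2e-05,0.91"), path)
  t <- read_quench_titration(path)
  expect_equal(attr(t, "temperature_K"), 288.15)
  expect_equal(nrow(t), 3)
})
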