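test_that("zero-enthalpy model yields a flat enthalpogram at the offset", {
  p <- dps_protocol()
  m <- micellization_model("pseudophase", cmc = 3.6e-3, dH_demic = 0,
                           dilution_offset = -150)
  e <- simulate_enthalpogram(p, m)
  expect_equal(e$q_J_per_mol, rep(-150, 32), tolerance = 1e-12)
})

test_that("pseudophase limiting regimes match the mass balance", {
  p <- dps_protocol()
  m <- micellization_model("pseudophase", cmc = 3.6e-3, dH_demic = 4000,
                           dilution_offset = -200)
  e <- simulate_enthalpogram(p, m)
  q_pre <- 4000 * (1 - 3.6e-3 / 0.04) - 200
  # early injections: cell far below CMC, all injected micelles dissolve
  expect_equal(e$q_J_per_mol[1:10], rep(q_pre, 10), tolerance = 1e-9)
  # late injections: cell far above CMC, only the dilution offset remains
  expect_equal(e$q_J_per_mol[25:32], rep(-200, 8), tolerance = 1e-9)
})

test_that("simulated heats conserve micellar mass at every injection", {
  p <- dps_protocol()
  for (m in list(dps_model("pseudophase"), dps_model("mass_action"))) {
    e <- simulate_enthalpogram(p, m)
    # reconstruct the per-injection demicellized amount from the heats and
    # verify the micellar balance: delivered = retained increase + expelled
    # + demicellized (all in moles), independently of the simulator's path
    f <- p$injection_volume / p$cell_volume
    C <- cell_concentration(p, 0:32)
    x <- itcmicelle:::model_monomer(m, C)
    mic <- C - x
    mic_syr <- p$syringe_conc - m$cmc
    n_inj <- moles_per_injection(p)
    dn <- (e$q_J_per_mol - m$dilution_offset) * n_inj / m$dH_demic
    delivered <- mic_syr * p$injection_volume
    expelled <- mic[1:32] * p$injection_volume
    retained <- (mic[2:33] - mic[1:32]) * p$cell_volume
    expect_lt(max(abs(delivered - expelled - retained - dn)) /
                max(delivered), 1e-9)
  }
})

test_that("noise is reproducible from the seed and scales as specified", {
  p <- dps_protocol()
  m <- dps_model()
  e1 <- simulate_enthalpogram(p, m, noise_spec(0.02, seed = 7L))
  e2 <- simulate_enthalpogram(p, m, noise_spec(0.02, seed = 7L))
  e3 <- simulate_enthalpogram(p, m, noise_spec(0.02, seed = 8L))
  expect_identical(e1$q_J_per_mol, e2$q_J_per_mol)
  expect_false(identical(e1$q_J_per_mol, e3$q_J_per_mol))
  e0 <- simulate_enthalpogram(p, m)
  resid <- e1$q_J_per_mol - e0$q_J_per_mol
  expect_lt(stats::sd(resid) / (0.02 * 4000), 2)
  expect_gt(stats::sd(resid) / (0.02 * 4000), 0.5)
  # the global RNG stream is untouched
  set.seed(123); before <- stats::rnorm(1)
  set.seed(123); invisible(simulate_enthalpogram(p, m, noise_spec(0.02, 1L)))
  expect_identical(stats::rnorm(1), before)
})

test_that("a protocol that never crosses the CMC warns", {
  p <- titration_protocol(syringe_conc = 0.04, n_injections = 5L)
  m <- micellization_model("pseudophase", cmc = 3e-2, dH_demic = 4000)
  expect_warning(simulate_enthalpogram(p, m), "never exceeds")
  expect_error(simulate_enthalpogram(
    p, micellization_model("pseudophase", cmc = 0.05, dH_demic = 1)),
    "demicellization")
})

test_that("power traces integrate back to the injection heats", {
  p <- dps_protocol()
  # single pulse normalisation: integral equals the heat to < 0.1%
  e1 <- enthalpogram(2.29e-4, 5000, temperature = 298.15)
  t1 <- simulate_power_trace(e1, p, peak_width = 40)
  Q <- 5000 * moles_per_injection(p)
  expect_equal(pracma::trapz(t1$times, t1$powers), Q, tolerance = 1e-3)
  # zero-heat enthalpogram renders the pure baseline
  e0 <- enthalpogram(c(2.29e-4, 4.5e-4), c(0, 0))
  t0 <- simulate_power_trace(e0, p, baseline_drift = 1e-9,
                             baseline_power = 5e-7)
  expect_equal(t0$powers, 5e-7 + 1e-9 * t0$times, tolerance = 1e-12)
  # full round trip through integrate_peaks, on a drifting baseline
  m <- dps_model()
  e <- simulate_enthalpogram(p, m)
  tg <- simulate_power_trace(e, p, peak_width = 40, baseline_drift = 2e-9,
                             baseline_power = 1e-6)
  e2 <- integrate_peaks(tg, p)
  expect_lt(max(abs(e2$q_J_per_mol - e$q_J_per_mol)) /
              max(abs(e$q_J_per_mol)), 0.01)
  expect_equal(e2$conc_mol_per_L, e$conc_mol_per_L, tolerance = 1e-12)
  expect_error(simulate_power_trace(e, p, peak_width = 400), "spacing")
})

test_that("temperature series are exactly linear and cross zero at T_H", {
  s <- simulate_temperature_series(-400, 290.65, c(283.15, 298.15, 308.15))
  expect_equal(s$dH_mic_J_per_mol[1], 3000, tolerance = 1e-12)
  expect_equal(simulate_temperature_series(-400, 290.65,
                                           c(290.65, 300))$dH_mic_J_per_mol[1],
               0, tolerance = 1e-12)
  expect_warning(simulate_temperature_series(-400, 290, c(283, 283, 300)),
                 "duplicate")
  expect_error(suppressWarnings(
    simulate_temperature_series(-400, 290, c(283, 283))), "distinct")
  # round trip through heat_capacity is exact for collinear points
  hc <- heat_capacity(s)
  expect_equal(hc$dCp, -400, tolerance = 1e-9)
  expect_equal(hc$T_H, 290.65, tolerance = 1e-9)
})
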