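test_that("micellization enthalpy is the negated demicellization enthalpy", {
  expect_identical(micellization_enthalpy(10000), -10000)
  expect_identical(micellization_enthalpy(0), 0)
  expect_identical(micellization_enthalpy(micellization_enthalpy(-321.5)),
                   -321.5)
})

test_that("gibbs_energy follows RT ln(cmc/c_std)", {
  expect_equal(gibbs_energy(1, 298.15), 0)
  expect_equal(gibbs_energy(3.6e-3, 298.15), -13947, tolerance = 1e-4)
  # logarithm law: halving the cmc shifts dG by RT ln(1/2) exactly
  d <- gibbs_energy(1.8e-3, 298.15) - gibbs_energy(3.6e-3, 298.15)
  expect_equal(d, 8.314 * 298.15 * log(0.5), tolerance = 1e-12)
  # strictly increasing in cmc
  expect_true(all(diff(gibbs_energy(c(1e-4, 1e-3, 1e-2, 1e-1), 310)) > 0))
  expect_error(gibbs_energy(0, 298.15), "positive")
  # c_std shift law: moving to a mole-fraction standard state shifts all
  # values by the same additive constant
  cmcs <- c(1e-3, 3.6e-3, 1.5e-3)
  shift <- gibbs_energy(cmcs, 298.15, c_std = 55.5) -
    gibbs_energy(cmcs, 298.15)
  expect_equal(shift, rep(-8.314 * 298.15 * log(55.5), 3), tolerance = 1e-12)
})

test_that("entropy terms close the decomposition identity", {
  ent <- entropy_terms(-13950, -4000, 298.15)
  expect_equal(ent$minus_TdS, -9950)
  expect_equal(ent$dS, 9950 / 298.15, tolerance = 1e-12)
  expect_equal(ent$dS, 33.37, tolerance = 1e-3)
  # linearity in (dG, dH)
  k <- 2.5
  ent_k <- entropy_terms(-13950 * k, -4000 * k, 298.15)
  expect_equal(ent_k$minus_TdS, k * ent$minus_TdS)
  expect_equal(ent_k$dS, k * ent$dS)
  expect_equal(entropy_terms(-5000, -5000, 310)$dS, 0)
})

test_that("decomposition closure holds over random records", {
  set.seed(99)
  for (i in 1:120) {
    rec <- thermo_record("cond", stats::runif(1, 278, 320),
                         10^stats::runif(1, -4, -2),
                         stats::runif(1, -20000, 20000))
    gap <- rec$dG_J_per_mol - rec$dH_mic_J_per_mol - rec$minus_TdS_J_per_mol
    expect_lt(abs(gap), 1e-9 * max(abs(rec$dG_J_per_mol), 1))
    expect_lt(rec$dG_J_per_mol, 0)  # cmc < c_std = 1 M
  }
})

test_that("heat_capacity reproduces the two-point closed form", {
  hc <- heat_capacity(data.frame(temperature_K = c(283.15, 308.15),
                                 dH_mic_J_per_mol = c(3000, -7000)))
  expect_equal(hc$dCp, -400, tolerance = 1e-10)
  expect_equal(hc$T_H, 290.65, tolerance = 1e-10)
  expect_false(hc$extrapolated)
  expect_true(is.na(hc$slope_stderr))
})

test_that("heat_capacity handles flat series and degenerate input", {
  hc <- heat_capacity(data.frame(temperature_K = c(283, 298, 308),
                                 dH_mic_J_per_mol = rep(5000, 3)))
  expect_equal(hc$dCp, 0, tolerance = 1e-9)
  expect_true(is.na(hc$T_H))
  expect_error(heat_capacity(data.frame(temperature_K = rep(298, 3),
                                        dH_mic_J_per_mol = 1:3)),
               "distinct")
})

test_that("heat_capacity flags far-extrapolated T_H", {
  s <- simulate_temperature_series(-50, 400, c(283.15, 298.15, 308.15))
  hc <- heat_capacity(s)
  expect_equal(hc$T_H, 400, tolerance = 1e-6)
  expect_true(hc$extrapolated)
})

test_that("least-squares dCp matches a brute-force grid minimiser", {
  set.seed(7)
  for (i in 1:10) {
    Tk <- sort(stats::runif(4, 278, 318))
    dH <- -400 * (Tk - 295) + stats::rnorm(4, sd = 300)
    hc <- heat_capacity(data.frame(temperature_K = Tk,
                                   dH_mic_J_per_mol = dH))
    # coarse-to-fine grid search over (slope, intercept-at-295)
    sl <- seq(hc$dCp - 50, hc$dCp + 50, length.out = 201)
    ic <- seq(-2000, 2000, length.out = 201)
    best <- c(NA, Inf)
    for (a in sl) for (b in ic) {
      r <- sum((dH - (a * (Tk - 295) + b))^2)
      if (r < best[2]) best <- c(a, r)
    }
    rss_lm <- sum((dH - (hc$dCp * Tk + hc$intercept))^2)
    expect_lte(rss_lm, best[2] * (1 + 1e-6))
  }
})

test_that("synthetic series are endothermic below T_H, exothermic above", {
  s <- simulate_temperature_series(-400, 298, c(283.15, 290, 305, 318))
  hc <- heat_capacity(s)
  expect_true(all(s$dH_mic_J_per_mol[s$temperature_K < 298] > 0))
  expect_true(all(s$dH_mic_J_per_mol[s$temperature_K > 298] < 0))
  expect_lt(hc$dCp, 0)
})
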