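test_that("eval_sigmoid has the right midpoint, asymptotes and degeneracy", {
  par <- c(a1 = 3000, a2 = 0, a3 = -200, a4 = 0, a5 = 3.6e-3, a6 = 1.5e-4)
  expect_equal(eval_sigmoid(par, 3.6e-3), (3000 - 200) / 2)
  expect_equal(eval_sigmoid(par, 3.6e-3 - 50 * 1.5e-4), 3000,
               tolerance = 1e-12)
  expect_equal(eval_sigmoid(par, 3.6e-3 + 50 * 1.5e-4), -200,
               tolerance = 1e-12)
  # sloping asymptotes
  par2 <- c(a1 = 3000, a2 = 2e5, a3 = -200, a4 = -1e5, a5 = 3.6e-3,
            a6 = 1e-4)
  expect_equal(eval_sigmoid(par2, 1e-4), 3000 + 2e5 * 1e-4, tolerance = 1e-9)
  expect_equal(eval_sigmoid(par2, 8e-3), -200 - 1e5 * 8e-3, tolerance = 1e-6)
  # a1 = a3, a2 = a4: exactly linear for all C
  par3 <- c(a1 = 1000, a2 = 5e4, a3 = 1000, a4 = 5e4, a5 = 3e-3, a6 = 2e-4)
  Cs <- seq(0, 7e-3, length.out = 11)
  expect_equal(eval_sigmoid(par3, Cs), 1000 + 5e4 * Cs, tolerance = 1e-12)
  expect_error(eval_sigmoid(c(par[1:5], a6 = -1), 1e-3), "positive")
})

test_that("parameters are recovered exactly from noiseless sigmoid data", {
  par <- c(a1 = 3400, a2 = -3e4, a3 = -150, a4 = -2e4, a5 = 3.5e-3,
           a6 = 2e-4)
  Cs <- seq(2e-4, 6.7e-3, length.out = 32)
  e <- enthalpogram(Cs, eval_sigmoid(par, Cs))
  fit <- fit_sigmoid(e)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), unname(par), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-8)
  # covariance is symmetric and positive semidefinite
  expect_false(anyNA(fit$covariance))
  expect_equal(fit$covariance, t(fit$covariance))
  ev <- eigen(fit$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-8 * max(abs(ev))))
})

test_that("flat-baseline fits put the CMC exactly at a5", {
  # equal baseline slopes: the derivative extremum is a5 itself, exactly
  par <- c(a1 = 3400, a2 = 0, a3 = -150, a4 = 0, a5 = 3.5e-3, a6 = 2e-4)
  ext <- itcmicelle:::derivative_extremum(par, c(2e-4, 6.7e-3))
  expect_identical(ext$cmc, 3.5e-3)
  # fitted slopes are zero only to convergence tolerance, so the fitted CMC
  # matches a5 to numerical precision rather than identically
  Cs <- seq(2e-4, 6.7e-3, length.out = 32)
  fit <- fit_sigmoid(enthalpogram(Cs, eval_sigmoid(par, Cs)))
  expect_equal(cmc_from_fit(fit), unname(coef(fit)["a5"]), tolerance = 1e-8)
  expect_equal(dH_from_fit(fit), 3400 - (-150), tolerance = 1e-4)
})

test_that("analytic derivative extremum matches a dense grid search", {
  set.seed(41)
  rng <- c(2e-4, 6.7e-3)
  grid <- seq(rng[1], rng[2], length.out = 1e5)
  step <- diff(rng) / (1e5 - 1)
  for (i in 1:25) {
    par <- random_sigmoid_params()
    ext <- itcmicelle:::derivative_extremum(par, rng)
    g <- abs(itcmicelle:::sigmoid_deriv(par, grid))
    expect_lt(abs(ext$cmc - grid[which.max(g)]), step + 1e-15,
              label = sprintf("draw %d", i))
  }
})

test_that("heats scale and flip without moving the CMC", {
  p <- dps_protocol()
  e <- simulate_enthalpogram(p, dps_model())
  f0 <- fit_sigmoid(e)
  # scale equivariance: q -> k*q scales dH by k, leaves cmc
  k <- 3.7
  ek <- enthalpogram(e$conc_mol_per_L, k * e$q_J_per_mol)
  fk <- fit_sigmoid(ek)
  expect_equal(cmc_from_fit(fk), cmc_from_fit(f0), tolerance = 1e-8)
  expect_equal(dH_from_fit(fk), k * dH_from_fit(f0), tolerance = 1e-6)
  # direction-agnostic: negating heats negates dH, preserves cmc
  en <- enthalpogram(e$conc_mol_per_L, -e$q_J_per_mol)
  fn <- fit_sigmoid(en)
  expect_equal(cmc_from_fit(fn), cmc_from_fit(f0), tolerance = 1e-8)
  expect_equal(dH_from_fit(fn), -dH_from_fit(f0), tolerance = 1e-6)
  # concentration-unit equivariance: mol/L -> mmol/L scales cmc by 1e3
  em <- enthalpogram(e$conc_mol_per_L * 1e3, e$q_J_per_mol)
  fm <- fit_sigmoid(em)
  expect_equal(cmc_from_fit(fm), 1e3 * cmc_from_fit(f0), tolerance = 1e-6)
  expect_equal(dH_from_fit(fm), dH_from_fit(f0), tolerance = 1e-6)
})

test_that("degenerate inputs are refused with informative errors", {
  Cs <- seq(2e-4, 6.7e-3, length.out = 32)
  expect_error(fit_sigmoid(enthalpogram(Cs[1:6], rep(1, 6) * Cs[1:6])),
               "at least 8")
  flat <- enthalpogram(Cs, rep(1000, 32))
  expect_error(fit_sigmoid(flat), "no transition")
})

test_that("noisy replicates recover the CMC with small median bias", {
  p <- dps_protocol()
  m <- dps_model()
  errs <- vapply(1:40, function(s) {
    e <- simulate_enthalpogram(p, m, noise_spec(0.02, seed = s))
    fit <- tryCatch(suppressWarnings(fit_sigmoid(e)),
                    error = function(err) NULL)
    if (is.null(fit)) return(NA_real_)
    cmc_from_fit(fit) / m$cmc - 1
  }, numeric(1))
  expect_lt(mean(is.na(errs)), 0.05)
  expect_lt(abs(stats::median(errs, na.rm = TRUE)), 0.05)
})
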