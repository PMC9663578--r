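test_that("fractional occupancy follows the competitive isotherm", {
  # half-saturation and the saturation limit
  expect_equal(fractional_occupancy(binding_params(kd = 0.8, probe_conc = 0.8)), 0.5)
  expect_equal(fractional_occupancy(binding_params(kd = 0.8, probe_conc = 0.8 * 1e7)),
               1.0, tolerance = 1e-5)
  expect_equal(fractional_occupancy(binding_params(kd = 0.8, probe_conc = 0)), 0)

  # hand-evaluated competition: 5 / (5 + 0.8 * (1 + 50/0.5))
  th <- fractional_occupancy(binding_params(kd = 0.8, probe_conc = 5,
                                            competitor_conc = 50,
                                            ki_competitor = 0.5))
  expect_equal(th, 5 / (5 + 0.8 * 101))
  expect_equal(round(th, 4), 0.0583)

  # zero competitor reduces exactly to the one-site isotherm
  for (kd in c(0.3, 0.8, 2.7, 6.6)) {
    for (p in c(0.1, 1, 5, 50)) {
      expect_identical(
        fractional_occupancy(binding_params(kd, p, 0, ki_competitor = 1)),
        p / (p + kd))
    }
  }
})

test_that("occupancy is monotone in probe and competitor concentrations", {
  withr::with_seed(11, {
    for (i in 1:25) {
      kd <- runif(1, 0.1, 10); ki <- runif(1, 0.05, 5)
      p <- sort(runif(2, 0.1, 50))
      occ <- vapply(p, function(pc)
        fractional_occupancy(binding_params(kd, pc, 10, ki)), numeric(1))
      expect_lt(occ[1], occ[2])
      i_conc <- sort(runif(2, 0.1, 100))
      occ_i <- vapply(i_conc, function(ic)
        fractional_occupancy(binding_params(kd, 5, ic, ki)), numeric(1))
      expect_gt(occ_i[1], occ_i[2])
    }
  })
})

test_that("invalid binding parameters are rejected", {
  expect_error(binding_params(kd = 0), "positive")
  expect_error(binding_params(kd = -1), "positive")
  expect_error(binding_params(kd = 1, probe_conc = -5), "non-negative")
  expect_error(binding_params(kd = 1, competitor_conc = 10, ki_competitor = NULL),
               "ki_competitor")
  expect_error(binding_params(kd = 1, competitor_conc = 10, ki_competitor = -2),
               "positive")
})

test_that("saturation binding fit recovers parameters", {
  conc <- c(0.1, 0.25, 0.5, 1, 2, 4, 8, 16)
  resp <- 100 * conc / (conc + 0.8)
  fit <- saturation_binding_fit(conc, resp)
  expect_equal(fit$kd, 0.8, tolerance = 1e-6)
  expect_equal(fit$bmax, 100, tolerance = 1e-6)

  # 5% multiplicative noise, 200 replicates: median Kd within 10% of truth
  withr::with_seed(21, {
    kds <- replicate(200, {
      noisy <- resp * rlnorm(length(resp), 0, 0.05)
      saturation_binding_fit(conc, noisy)$kd
    })
  })
  expect_lt(abs(median(kds) - 0.8) / 0.8, 0.10)

  expect_error(saturation_binding_fit(conc, rep(50, 8)), "constant")
  expect_error(saturation_binding_fit(conc[1:3], resp[1:3]), "4 distinct")
})

test_that("four-parameter logistic forward model and IC50 fit agree", {
  pr <- dose_response_params(ic50 = 4.0, hill = 1, top = 1, bottom = 0)
  # at c = ic50 the response is the (top + bottom) / 2 midpoint
  expect_equal(four_param_logistic(4.0, pr), 0.5)
  expect_equal(four_param_logistic(10, dose_response_params(10, 2, 0.9, 0.1)), 0.5)

  # noiseless recovery at both affinity regimes used in the kinase assays
  for (true_ic50 in c(4.0, 977)) {
    conc <- 10^seq(log10(true_ic50) - 2.5, log10(true_ic50) + 2.5, length.out = 9)
    y <- four_param_logistic(conc, dose_response_params(true_ic50))
    fit <- fit_ic50(conc, y)
    expect_equal(fit$params$ic50, true_ic50, tolerance = 1e-6)
    expect_equal(fit$params$hill, 1, tolerance = 1e-5)
  }
  expect_error(fit_ic50(c(1, 2, 4, 8, 16), rep(0.5, 5)), "identical")
  expect_error(fit_ic50(c(1, 2, 4), c(1, 0.5, 0)), "at least 5")
})

test_that("fits are consistent: bias shrinks with the noise level", {
  conc <- c(0.1, 0.25, 0.5, 1, 2, 4, 8, 16)
  resp <- 100 * conc / (conc + 0.8)
  bias <- vapply(c(0.10, 0.02, 0), function(cv) {
    withr::with_seed(31, {
      kds <- replicate(60, {
        noisy <- resp * rlnorm(length(resp), 0, cv)
        saturation_binding_fit(conc, noisy)$kd
      })
    })
    abs(median(kds) - 0.8)
  }, numeric(1))
  expect_true(all(diff(bias) <= 0))
  expect_lt(bias[3], 1e-6)
})

test_that("expected cell fluorescence is affine in active receptors x occupancy", {
  fl <- fluorophore_model()
  expect_equal(expected_cell_fluorescence(1e5, 0, fl), fl$autofluorescence_mean)

  base <- expected_cell_fluorescence(1e4, 0.5, fl) - fl$autofluorescence_mean
  dbl <- expected_cell_fluorescence(2e4, 0.5, fl) - fl$autofluorescence_mean
  expect_equal(dbl, 2 * base)

  # turn-on contrast is the bound/free quantum-yield quotient
  expect_equal(fl$phi_bound / fl$phi_free, 42.4 / 5.8)
  expect_equal(round(fl$phi_bound / fl$phi_free, 2), 7.31)

  # affinity: signal - autofluorescence proportional to n * occupancy
  n <- c(0, 1e3, 5e4); occ <- c(0.1, 0.9, 0.5)
  sig <- expected_cell_fluorescence(n, occ, fl)
  expect_equal(sig - fl$autofluorescence_mean,
               fl$per_molecule_gain * (fl$phi_bound / fl$phi_free) * n * occ)
})
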