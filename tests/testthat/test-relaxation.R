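# Decay fitting, correlation times, apparent MW, exchange diagnostics.

paper_t1_delays <- relaxation_delays("paper_T1")

test_that("noiseless exponential decays are recovered exactly", {
  curve <- 100 * exp(-10 * paper_t1_delays / 1000)
  fit <- fit_monoexponential(paper_t1_delays, curve)
  expect_equal(fit$rate, 10, tolerance = 1e-6)
  expect_equal(fit$amplitude, 100, tolerance = 1e-6)
  expect_equal(fit$fit_quality, 1, tolerance = 1e-9)
  expect_false(fit$flagged)
})

test_that("rates survive 1% multiplicative noise within 2%", {
  errs <- vapply(1:100, function(s) {
    ser <- gen_relaxation_decays(c(`1` = 10), paper_t1_delays,
                                 noise_frac = 0.01, seed = s)
    d <- ser$data
    abs(fit_monoexponential(d$delay_ms, d$intensity)$rate - 10) / 10
  }, 1.0)
  expect_lt(stats::median(errs), 0.02)
  expect_lt(sqrt(mean(errs^2)), 0.02)   # RMS relative error
})

test_that("degenerate curves are flagged rather than fitted", {
  flat <- fit_monoexponential(paper_t1_delays, rep(55, 9))
  expect_equal(flat$rate, 0)
  expect_true(flat$flagged)
  expect_error(fit_monoexponential(c(1, 2, 3), c(3, 2, 1)),
               class = "nmrdomain_value_error")
})

test_that("the R2/R1 estimator matches its closed form and domain", {
  # root boundary: ratio exactly 7/9 is invalid, just above is ~0
  expect_error(tauc_from_ratio(7, 9, 60.81e6),
               class = "nmrdomain_domain_error")
  expect_lt(tauc_from_ratio(7.001, 9, 60.81e6), 0.05)
  expect_equal(tauc_from_ratio(4, 1, 60.81e6), 5.754, tolerance = 1e-3)
  expect_error(tauc_from_ratio(0.5, 1, 60.81e6),
               class = "nmrdomain_domain_error")
  expect_error(tauc_from_ratio(4, 0, 60.81e6),
               class = "nmrdomain_value_error")
  # strictly increasing in R2/R1 at fixed nu_N
  ratios <- seq(1.5, 20, 0.5)
  tc <- tauc_from_ratio(ratios, 1, 60.81e6)
  expect_true(all(diff(tc) > 0))
  # the classical reading differs only modestly in the relevant range
  tc_c <- tauc_from_ratio(4, 1, 60.81e6, formula = "classical")
  expect_lt(abs(tc_c - 5.754) / 5.754, 0.08)
})

test_that("spectral-density oracle reproduces independently computed rates", {
  # frozen values from an external numeric evaluation of the dipolar+CSA
  # expressions (tau_c = 5.3 ns, S2 = 1, 600 MHz, r = 1.02 A, CSA -160 ppm)
  r <- simulate_relaxation_rates(5.3, 600)
  expect_equal(r$r1, 2.1803, tolerance = 1e-4)
  expect_equal(r$r2, 8.3856, tolerance = 1e-4)
  expect_equal(r$r2 / r$r1, 3.8460, tolerance = 1e-4)
  expect_equal(r$noe, 0.8844, tolerance = 1e-3)
})

test_that("tau_c to MW conversion is linear with the 0.6 ns/kDa factor", {
  expect_equal(mw_from_tauc(6), 10)
  expect_equal(mw_from_tauc(0), 0)
  expect_equal(mw_from_tauc(5.3), 8.83, tolerance = 1e-3)
  for (mw in c(0, 1, 5.87, 23)) expect_equal(mw_from_tauc(0.6 * mw), mw)
  expect_error(mw_from_tauc(-1), class = "nmrdomain_value_error")
})

test_that("domain averages honour rigid-residue filters and flag exchange", {
  r1 <- rate_profile_from(1:10, rep(2.18, 10), experiment = "T1")
  r2 <- rate_profile_from(1:10, rep(8.39, 10), experiment = "T2")
  nu <- nitrogen_larmor(600)
  res <- domain_tauc(r1, r2, nu)
  expect_equal(res$tau_c_sd, 0)
  expect_equal(res$n, 10)
  expect_equal(res$apparent_mw, res$tau_c / 0.6)
  expect_false(res$r1rho_based)

  # flexible termini excluded via the hetNOE profile
  noe <- hetnoe_profile(1:10, c(0.2, 0.3, rep(0.8, 6), 0.3, 0.2))
  res_f <- domain_tauc(r1, r2, nu, hetnoe = noe)
  expect_equal(res_f$n, 6)
  expect_equal(res_f$per_residue$residue, 3:8)

  # R1rho stands in for R2 and is flagged as such
  r1rho <- rate_profile_from(1:10, rep(7.9, 10), experiment = "T1rho")
  expect_true(domain_tauc(r1, r1rho, nu)$r1rho_based)

  expect_error(domain_tauc(r1, r2, nu, include = 99),
               class = "nmrdomain_value_error")
})

test_that("exchange flag fires on a relative R2 spread above 50%", {
  quiet <- rate_profile_from(1:3, c(10, 10, 10))
  expect_false(exchange_diagnostic(quiet)$flagged)
  expect_equal(exchange_diagnostic(quiet)$relative_sd, 0)

  # mean 10, SD 6
  spread <- rate_profile_from(1:3, c(4, 10, 16))
  d <- exchange_diagnostic(spread)
  expect_equal(d$relative_sd, 0.6, tolerance = 1e-12)
  expect_true(d$flagged)

  # just under the threshold
  mild <- rate_profile_from(1:5, c(10, 10, 10, 10, 21))
  expect_lt(exchange_diagnostic(mild)$relative_sd, 0.5)
  expect_false(exchange_diagnostic(mild)$flagged)

  expect_error(exchange_diagnostic(rate_profile_from(1:2, c(1, 2))),
               class = "nmrdomain_value_error")
})
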