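# Synthetic-data generators: isotherm, spin physics, determinism, ground
# truth recovery in the noiseless limit.

test_that("the single-site isotherm solves the binding quadratic", {
  expect_equal(fraction_bound(0.1, 0, 0.01), 0)
  expect_gt(fraction_bound(0.1, 100, 0.001), 0.99)
  expect_equal(fraction_bound(0.1, 0.1, 0.01), 0.7298, tolerance = 1e-4)
  # monotonic in ligand, decreasing in Kd, bounded
  l <- seq(0, 1, 0.05)
  fb <- fraction_bound(0.1, l, 0.01)
  expect_true(all(diff(fb) >= 0))
  expect_true(all(fb >= 0 & fb <= 1))
  expect_true(all(fraction_bound(0.1, l, 0.1) <= fb + 1e-12))
  expect_error(fraction_bound(0, 1, 1), class = "nmrdomain_value_error")
})

test_that("titrations reach the endpoint vector in the stoichiometric limit", {
  base <- gen_peaklist(1:20, seed = 5)
  binders <- data.frame(residue_number = 7, d_h_max = 0.2, d_n_max = 0.8)
  ser <- gen_titration(base, binders, kd = 1e-6, protein_conc = 0.1,
                       ratios = c(0, 1), noise_ppm = 0)
  apo <- ser$points[[1]]; one <- ser$points[[2]]
  i <- match(7, apo$residue_number)
  expect_equal(one$h_ppm[i] - apo$h_ppm[i], 0.2, tolerance = 0.01)
  expect_equal(one$n_ppm[i] - apo$n_ppm[i], 0.8, tolerance = 0.04)
  # non-binders do not move at all without noise
  expect_equal(one$h_ppm[-i], apo$h_ppm[-i])

  expect_error(gen_titration(base, binders, ratios = c(1, 2)),
               class = "nmrdomain_value_error")
  expect_error(gen_titration(base,
                             data.frame(residue_number = 99,
                                        d_h_max = 1, d_n_max = 1)),
               class = "nmrdomain_value_error")
})

test_that("fast-exchange trajectories are collinear across ratios", {
  base <- gen_peaklist(1:30, seed = 8)
  binders <- data.frame(residue_number = c(5, 12, 20),
                        d_h_max = c(0.25, -0.2, 0.15),
                        d_n_max = c(0.8, 0.5, -1.2))
  ser <- gen_titration(base, binders, noise_ppm = 0, seed = 1)
  apo <- ser$points[[1]]
  profs <- lapply(ser$points[-1], function(p) compute_csp(apo, p))
  for (k in seq_along(profs)[-1]) {
    ts <- suppressMessages(
      trajectory_similarity(profs[[k - 1]], profs[[k]]))
    keep <- ts$residue_number %in% binders$residue_number
    expect_true(all(ts$cosine[keep] >= 0.999))
  }
})

test_that("oracle rates behave physically across the tumbling regime", {
  grid <- c(0.3, 1, 2, 5, 8, 12)
  for (field in c(600, 950)) {
    rr <- vapply(grid, function(tc)
      unlist(simulate_relaxation_rates(tc, field)[c("r1", "r2")]),
      numeric(2))
    expect_true(all(rr[2, ] >= rr[1, ]))          # R2 >= R1
    expect_true(all(diff(rr[2, ] / rr[1, ]) > 0)) # ratio increasing in tau_c
  }
  # extreme narrowing: R2/R1 -> 1
  fast <- simulate_relaxation_rates(0.01, 600)
  expect_equal(fast$r2 / fast$r1, 1, tolerance = 0.02)
  # exchange adds to R2 only
  base <- simulate_relaxation_rates(5.3, 600)
  rex <- simulate_relaxation_rates(5.3, 600, rex = 5)
  expect_equal(rex$r2 - base$r2, 5, tolerance = 1e-9)
  expect_equal(rex$r1, base$r1)
  expect_error(simulate_relaxation_rates(-1, 600),
               class = "nmrdomain_value_error")
  expect_error(simulate_relaxation_rates(5, 600, s2 = 1.5),
               class = "nmrdomain_value_error")
})

test_that("decay generator presets and noiseless fits are exact", {
  d <- relaxation_delays("paper_T1")
  expect_length(d, 9)
  expect_equal(d[1], 20)
  expect_equal(d[9], 1400)
  expect_length(relaxation_delays("paper_T1rho"), 9)

  ser <- gen_relaxation_decays(c(`3` = 4.2, `4` = 7.7), d)
  rates <- fit_rates(ser)
  expect_equal(rates$rate, c(4.2, 7.7), tolerance = 1e-6)
  expect_error(gen_relaxation_decays(c(`1` = 2), numeric(0)),
               class = "nmrdomain_value_error")
  expect_error(gen_relaxation_decays(c(`1` = -2), d),
               class = "nmrdomain_value_error")
})

test_that("planted secondary structure is recovered exactly without noise", {
  seqn <- strrep("ADEFKLQSTV", 4)
  sse <- data.frame(kind = c("helix", "strand"), start = c(8, 20),
                    end = c(13, 27))
  tab <- gen_scs_dataset(seqn, 1, sse, noise_ppm = 0)
  called <- call_sse(compute_scs(tab))
  expect_equal(as.data.frame(called)[, c("kind", "start", "end")], sse,
               ignore_attr = TRUE)

  # no elements, no noise: combined SCS identically zero
  flat <- gen_scs_dataset(seqn, 1, NULL, noise_ppm = 0)
  expect_equal(compute_scs(flat)$combined_scs, rep(0, 40), tolerance = 1e-12)

  overlap <- data.frame(kind = c("helix", "strand"), start = c(5, 8),
                        end = c(10, 12))
  expect_error(gen_scs_dataset(seqn, 1, overlap),
               class = "nmrdomain_value_error")
})

test_that("all generators are deterministic under a fixed seed", {
  base <- gen_peaklist(1:15, seed = 2)
  binders <- data.frame(residue_number = 4, d_h_max = 0.2, d_n_max = 0.6)
  t1 <- gen_titration(base, binders, noise_ppm = 0.02, seed = 33)
  t2 <- gen_titration(base, binders, noise_ppm = 0.02, seed = 33)
  expect_identical(t1, t2)

  expect_identical(gen_relaxation_decays(c(`1` = 9), noise_frac = 0.02,
                                         seed = 4),
                   gen_relaxation_decays(c(`1` = 9), noise_frac = 0.02,
                                         seed = 4))
  expect_identical(gen_scs_dataset("ACDEF", 1, NULL, noise_ppm = 0.3,
                                   seed = 6),
                   gen_scs_dataset("ACDEF", 1, NULL, noise_ppm = 0.3,
                                   seed = 6))
  expect_identical(gen_hetnoe_dataset(noise = 0.05, seed = 9),
                   gen_hetnoe_dataset(noise = 0.05, seed = 9))
  expect_identical(gen_sec_run(noise_ml = 0.05, seed = 12),
                   gen_sec_run(noise_ml = 0.05, seed = 12))
  # and the caller's RNG stream is untouched
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(gen_peaklist(1:5, seed = 77))
  expect_identical(stats::runif(1), before)
})

test_that("noiseless hetNOE and SEC runs return their ground truth", {
  prof <- gen_hetnoe_dataset(residues = 18:70, core = c(30, 67),
                             plateau = 0.8, terminal = 0.2, noise = 0)
  expect_equal(rigid_core(classify_flexibility(prof)),
               c(start = 30, end = 67))

  run <- gen_sec_run(samples = c(dimerish = 11), noise_ml = 0)
  cal <- fit_calibration(run$standards, run$v0, run$vc)
  expect_equal(estimate_mw(cal$standards$kav, cal), run$standards$mw_kda,
               tolerance = 1e-9)
  expect_equal(estimate_mw(compute_kav(run$samples$ve_ml, run$v0, run$vc),
                           cal),
               11, tolerance = 1e-9)
})
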