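# Peak matching, CSPs, significance, trajectories, fold and variants.

test_that("peak matching pairs by residue and flags jumps", {
  a <- spread_peaks(1:8)
  m <- match_peaks(a, a)
  expect_equal(nrow(m$pairs), 8)
  expect_equal(m$pairs$distance, rep(0, 8))
  expect_false(any(m$pairs$jump))

  b <- a; b$h_ppm[3] <- b$h_ppm[3] + 0.3
  m2 <- match_peaks(a, b, tol = 0.15)
  expect_true(m2$pairs$jump[m2$pairs$residue_number == 3])
  expect_equal(sum(m2$pairs$jump), 1)

  m3 <- match_peaks(spread_peaks(1:4), spread_peaks(11:14))
  expect_equal(nrow(m3$pairs), 0)
  expect_equal(m3$unmatched_a, 1:4)
  expect_equal(m3$unmatched_b, 11:14)

  expect_error(match_peaks(a, a, tol = 0), class = "nmrdomain_value_error")
})

test_that("nearest-neighbour matching recovers pairs without assignments", {
  a <- spread_peaks(1:6)
  b <- a
  b$residue_number <- b$residue_number + 100L  # unassigned relabelling
  b$h_ppm <- b$h_ppm + 0.01
  m <- match_peaks(a, b, tol = 0.15, method = "nearest")
  expect_equal(nrow(m$pairs), 6)
  expect_true(all(m$pairs$distance < 0.02))
})

test_that("CSP follows the 1/5 nitrogen-scaled combination", {
  apo <- flat_peaks(1:3)
  bound <- apo
  prof0 <- compute_csp(apo, bound)
  expect_equal(prof0$csp, rep(0, 3))

  bound$h_ppm <- apo$h_ppm + c(0.10, 0, 0)
  bound$n_ppm <- apo$n_ppm + c(0.50, 1.0, 0)
  prof <- compute_csp(apo, bound)
  expect_equal(prof$csp[1], 0.1414, tolerance = 1e-3)
  expect_equal(prof$csp[2], 0.20, tolerance = 1e-12)
  expect_equal(prof$csp[3], 0)
  expect_true(all(prof$csp >= 0))

  expect_error(compute_csp(flat_peaks(1:3), flat_peaks(11:13)),
               class = "nmrdomain_value_error")
})

test_that("CSP is invariant under a global referencing offset", {
  apo <- spread_peaks(1:6)
  bound <- apo
  bound$h_ppm <- bound$h_ppm + stats::runif(6, -0.1, 0.1)
  bound$n_ppm <- bound$n_ppm + stats::runif(6, -0.5, 0.5)
  ref <- compute_csp(apo, bound)
  apo2 <- apo; bound2 <- bound
  apo2$h_ppm <- apo2$h_ppm + 0.13; bound2$h_ppm <- bound2$h_ppm + 0.13
  apo2$n_ppm <- apo2$n_ppm - 0.8;  bound2$n_ppm <- bound2$n_ppm - 0.8
  expect_equal(compute_csp(apo2, bound2)$csp, ref$csp, tolerance = 1e-12)
})

test_that("significance thresholds use the population spread of all CSPs", {
  prof <- csp_profile_from(1:10, c(rep(0.10, 9), 0.60), rep(0, 10))
  sig <- csp_significance(prof, "mean_plus_two_sd")
  expect_equal(sig$threshold, 0.45, tolerance = 1e-12)
  expect_equal(sig$significant_residues, 10L)

  # uniform profiles never mark anything above mean-based thresholds
  flat <- csp_profile_from(1:5, rep(0.2, 5), rep(0, 5))
  expect_length(csp_significance(flat, "mean")$significant_residues, 0)
  expect_length(csp_significance(flat, "mean_plus_two_sd")$significant_residues, 0)
  zero <- csp_profile_from(1:5, rep(0, 5), rep(0, 5))
  expect_length(csp_significance(zero, "two_sd")$significant_residues, 0)

  expect_error(csp_significance(csp_profile_from(1:2, c(0, 1), c(0, 0))),
               class = "nmrdomain_value_error")
})

test_that("trajectory cosines separate direction from extent", {
  a <- csp_profile_from(1:6, c(0.2, -0.1, 0.3, 0.05, 0.15, -0.2),
                        c(0.5, 0.8, -1.0, 0.2, -0.4, 0.6))
  same <- trajectory_similarity(a, a)
  expect_equal(same$cosine, rep(1, 6), tolerance = 1e-12)

  half <- csp_profile_from(1:6, a$d_h * 0.5, a$d_n * 0.5)
  expect_equal(trajectory_similarity(a, half)$cosine, rep(1, 6),
               tolerance = 1e-12)

  neg <- csp_profile_from(1:6, -a$d_h, -a$d_n)
  expect_equal(trajectory_similarity(a, neg)$cosine, rep(-1, 6),
               tolerance = 1e-12)

  withzero <- csp_profile_from(1:6, c(0, a$d_h[-1]), c(0, a$d_n[-1]))
  expect_message(ts <- trajectory_similarity(a, withzero), "zero shift")
  expect_equal(nrow(ts), 5)
})

test_that("fold assessment separates dispersed from collapsed spectra", {
  set.seed(3)
  confined <- peak_list(1:20, rep("S", 20), stats::runif(20, 7.9, 8.4),
                        stats::runif(20, 115, 123))
  expect_equal(assess_fold(confined)$verdict, "collapsed")

  dispersed <- peak_list(1:20, rep("S", 20),
                         seq(6.5, 10.2, length.out = 20),
                         stats::runif(20, 105, 132))
  res <- assess_fold(dispersed)
  expect_equal(res$verdict, "folded")
  expect_gt(res$h_range, 1.5)

  expect_error(assess_fold(confined[1:5, ]),
               class = "nmrdomain_value_error")
})

test_that("variant comparison grades extent against conserved trajectories", {
  wt <- csp_profile_from(1:12,
                         c(rep(0.01, 9), 0.25, 0.30, 0.20),
                         c(rep(0.02, 9), 0.9, -0.8, 0.7))
  same <- compare_variant_binding(wt, wt)
  expect_equal(same$extent_ratio, 1.0)
  expect_equal(same$verdict, "wt_like")

  half <- csp_profile_from(1:12, wt$d_h * 0.5, wt$d_n * 0.5)
  red <- compare_variant_binding(wt, half)
  expect_equal(red$extent_ratio, 0.5, tolerance = 1e-12)
  expect_equal(red$verdict, "reduced")

  dead <- csp_profile_from(1:12, rep(1e-4, 12), rep(-1e-4, 12))
  expect_equal(compare_variant_binding(wt, dead)$verdict, "abolished")

  # comparable extent along different directions is nonspecific
  rot <- wt
  rot$d_h[10:12] <- wt$d_n[10:12] / 5
  rot$d_n[10:12] <- -wt$d_h[10:12] * 5
  rot$csp <- sqrt((rot$d_n / 5)^2 + rot$d_h^2)
  expect_equal(compare_variant_binding(wt, rot)$verdict, "nonspecific")

  flat <- csp_profile_from(1:12, rep(0.1, 12), rep(0, 12))
  expect_error(compare_variant_binding(flat, flat),
               class = "nmrdomain_value_error")
})

test_that("titration series require an apo start and increasing ratios", {
  pts <- list(flat_peaks(1:4), flat_peaks(1:4))
  expect_error(titration_series(pts, c(0.5, 1)),
               class = "nmrdomain_value_error")
  expect_error(titration_series(pts, c(0, 0)),
               class = "nmrdomain_value_error")
  ser <- titration_series(pts, c(0, 2))
  expect_s3_class(ser, "titration_series")
})
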