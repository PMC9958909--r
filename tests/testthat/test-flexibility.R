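# hetNOE ratios, flexibility classification and rigid-core detection.

test_that("hetNOE ratios are saturated over reference heights", {
  ref <- spread_peaks(1:10, height = 200)
  expect_equal(compute_hetnoe(ref, ref)$ratio, rep(1, 10))

  sat <- ref; sat$height <- 0.4 * ref$height
  expect_equal(compute_hetnoe(sat, ref)$ratio, rep(0.4, 10))

  # common rescaling of both lists cancels
  sat2 <- sat; sat2$height <- sat$height * 17.3
  ref2 <- ref; ref2$height <- ref$height * 17.3
  expect_equal(compute_hetnoe(sat2, ref2)$ratio,
               compute_hetnoe(sat, ref)$ratio)
})

test_that("zero reference heights are skipped and disjoint lists rejected", {
  ref <- spread_peaks(1:5, height = 100)
  ref$height[3] <- 0
  sat <- spread_peaks(1:5, height = 60)
  expect_warning(prof <- compute_hetnoe(sat, ref), "zero reference")
  expect_equal(prof$residue_number, c(1L, 2L, 4L, 5L))
  expect_error(compute_hetnoe(spread_peaks(1:3, height = 1),
                              spread_peaks(7:9, height = 1)),
               class = "nmrdomain_value_error")
  expect_error(compute_hetnoe(spread_peaks(1:3), spread_peaks(1:3)),
               class = "nmrdomain_value_error")  # no heights
})

test_that("ratio errors propagate relative noise in quadrature", {
  sat <- flat_peaks(1, height = 50)
  ref <- flat_peaks(1, height = 100)
  prof <- compute_hetnoe(sat, ref, sigma_sat = 5, sigma_ref = 2)
  expect_equal(prof$error, 0.5 * sqrt((5 / 50)^2 + (2 / 100)^2),
               tolerance = 1e-12)
})

test_that("flexibility labels follow the 0.5 / 0.65 thresholds", {
  prof <- hetnoe_profile(1:5, c(0.2, 0.45, 0.5, 0.6, 0.7))
  call <- classify_flexibility(prof)
  expect_equal(call$label, c("flexible", "flexible", "intermediate",
                             "intermediate", "rigid"))
  # labels depend on ratio only: identical ratios, different residues
  call2 <- classify_flexibility(hetnoe_profile(101:105,
                                               c(0.2, 0.45, 0.5, 0.6, 0.7)))
  expect_equal(call2$label, call$label)
})

test_that("rigid cores tolerate short interruptions", {
  # rigid 30-33 and 37-67, flexible 34-36: interruption of 3 tolerated
  res <- 18:70
  ratio <- ifelse(res >= 30 & res <= 67, 0.8, 0.2)
  ratio[res %in% 34:36] <- 0.3
  call <- classify_flexibility(hetnoe_profile(res, ratio))
  expect_equal(rigid_core(call, max_gap = 3), c(start = 30, end = 67))
  # with max_gap 2 the same interruption splits the core
  expect_equal(rigid_core(call, max_gap = 2), c(start = 37, end = 67))

  all_flex <- classify_flexibility(hetnoe_profile(1:10, rep(0.1, 10)))
  expect_null(rigid_core(all_flex))

  single <- classify_flexibility(hetnoe_profile(50, 0.9))
  expect_equal(rigid_core(single), c(start = 50, end = 50))

  expect_error(rigid_core(call, max_gap = -1),
               class = "nmrdomain_value_error")
})

test_that("missing residues count as interruptions", {
  res <- c(10:14, 20:24)   # gap of 5 unobserved residues
  call <- classify_flexibility(hetnoe_profile(res, rep(0.9, length(res))))
  expect_equal(rigid_core(call, max_gap = 3), c(start = 10, end = 14))
  expect_equal(rigid_core(call, max_gap = 5), c(start = 10, end = 24))
})
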