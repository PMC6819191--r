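test_that("ratcheting strain is the mean of valley and peak strain", {
  expect_equal(ratcheting_strain(0, 0), 0)
  expect_equal(ratcheting_strain(0.1, 0.3), 0.2)
  expect_equal(ratcheting_strain(-0.02, 0.06), 0.02)
  expect_error(ratcheting_strain(0.3, 0.1), "must not exceed")
})

test_that("segmentation yields one segment per complete commanded cycle", {
  prot <- loading_protocol(1.76, 1.18, n_cycles = 200)
  s <- generate_response(prot, specimen_params(seed = 3))
  expect_equal(nrow(segment_cycles(s, prot)), 200)

  # a series truncated mid-cycle drops the trailing partial segment
  k <- nrow(s) - prot$samples_per_ramp  # cut inside the last cycle
  s_trunc <- stress_strain_series(s$time_s[1:k], s$stress_MPa[1:k],
                                  s$strain[1:k], protocol = prot)
  expect_equal(nrow(segment_cycles(s_trunc, prot)), 199)

  # a single-cycle series gives one segment spanning the whole record
  prot1 <- loading_protocol(0.59, 0.59, n_cycles = 1)
  s1 <- generate_response(prot1, specimen_params(seed = 3))
  seg1 <- segment_cycles(s1, prot1)
  expect_equal(nrow(seg1), 1)
  expect_equal(seg1$start, 1)
  expect_equal(seg1$end, nrow(s1))

  # inconsistent time stamps are a segmentation error
  s_bad <- stress_strain_series(s$time_s * 1.31, s$stress_MPa, s$strain,
                                protocol = prot)
  expect_error(segment_cycles(s_bad, prot), "segmentation error")
})

test_that("ratcheting rate uses central differences, one-sided at the ends", {
  rc <- function(y) ratcheting_curve(seq_along(y), y)
  expect_equal(ratcheting_rate(rc(c(1, 2, 3, 4))), rep(1, 4))
  expect_equal(ratcheting_rate(rc(rep(2.5, 6))), rep(0, 6))
  # hand finite-difference oracle
  expect_equal(ratcheting_rate(rc(c(0, 1, 1.5, 1.75))),
               c(1, 0.75, 0.375, 0.25))
  expect_error(ratcheting_rate(rc(1)), "at least 2 cycles")
})

test_that("compression stiffness recovers E*S/h on a linear-elastic record", {
  prot <- loading_protocol(1.18, 0.59, n_cycles = 5)
  s <- generate_response(prot, elastic_params(E = 5))
  g <- sheep_geometry()
  expect_equal(compression_stiffness(s, g, cycle = 5, prot),
               5 * 394 / 3.98, tolerance = 1e-9)
  expect_equal(compression_stiffness(s, g, cycle = 5, prot), 494.9749,
               tolerance = 1e-6)
  # doubling the area doubles the stiffness
  g2 <- specimen_geometry(area = 2 * 394, height = 3.98)
  expect_equal(compression_stiffness(s, g2, cycle = 5, prot),
               2 * compression_stiffness(s, g, cycle = 5, prot))
  expect_error(compression_stiffness(s, g, cycle = 6, prot),
               "only 5 complete cycles")
  # zero displacement span is a degenerate cycle
  s_flat <- stress_strain_series(s$time_s, s$stress_MPa,
                                 rep(0, nrow(s)), protocol = prot)
  expect_error(compression_stiffness(s_flat, g, cycle = 1, prot),
               "degenerate")
})

test_that("valley <= ratcheting strain <= peak for every cycle of noisy data", {
  prot <- loading_protocol(0.88, 0.59, n_cycles = 30)
  s <- generate_response(prot, specimen_params(noise_sd = 2e-3, seed = 17))
  cs <- cycle_summaries(s, prot)
  expect_true(all(pmin(cs$strain_min, cs$strain_max) <=
                    cs$ratcheting_strain))
  expect_true(all(cs$ratcheting_strain <=
                    pmax(cs$strain_min, cs$strain_max)))
  expect_true(all(is.finite(cs$strain_range)))
})

test_that("metrics are invariant to uniform resampling of noise-free data", {
  base <- loading_protocol(1.18, 0.59, n_cycles = 20)
  fine <- loading_protocol(1.18, 0.59, n_cycles = 20,
                           sampling_rate = 2 * base$sampling_rate)
  c1 <- build_ratcheting_curve(generate_response(base, clean_params()), base)
  c2 <- build_ratcheting_curve(generate_response(fine, clean_params()), fine)
  expect_lt(max(abs(c1$ratcheting_strain - c2$ratcheting_strain)), 1e-6)
})

test_that("noise-free ratcheting curve rises with strictly positive rate", {
  prot <- loading_protocol(1.76, 1.18, n_cycles = 200)
  curve <- build_ratcheting_curve(generate_response(prot, clean_params()),
                                  prot)
  expect_true(all(diff(curve$ratcheting_strain) > 0))
  expect_true(all(curve$ratcheting_rate > 0))
})
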