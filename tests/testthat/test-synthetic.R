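test_that("pure elasticity gives strain proportional to stress, loops closed", {
  prot <- loading_protocol(1.18, 0.59, n_cycles = 5)
  s <- generate_response(prot, elastic_params(E = 5))
  expect_equal(s$strain, s$stress_MPa / 5, tolerance = 1e-12)
  cs <- cycle_summaries(s, prot)
  # every loop closed: valley strain identical across cycles
  expect_equal(diff(cs$strain_min), rep(0, 4))
})

test_that("generation is deterministic under a fixed seed", {
  prot <- loading_protocol(0.59, 0.4, n_cycles = 5)
  p <- specimen_params(noise_sd = 5e-4, seed = 123)
  s1 <- generate_response(prot, p)
  s2 <- generate_response(prot, p)
  expect_identical(s1$strain, s2$strain)
  # and identical bytes after serialization
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_series_csv(s1, f1); write_series_csv(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("stress channel reproduces the commanded waveform exactly", {
  prot <- loading_protocol(1.76, 1.18, n_cycles = 8)
  s <- generate_response(prot, specimen_params(seed = 2))
  expect_identical(s$stress_MPa, protocol_waveform(prot)$stress_MPa)
})

test_that("hysteresis loops densify and stay unclosed under ratcheting", {
  prot <- loading_protocol(1.76, 1.18, n_cycles = 200)
  s <- generate_response(prot, clean_params())
  cs <- cycle_summaries(s, prot)
  expect_equal(nrow(cs), 200)
  # strain range non-increasing after cycle 1 (loops densify)
  expect_true(all(diff(cs$strain_range) <= 1e-12))
  # the 200th loop is not closed: closing-valley strain exceeds opening
  seg <- segment_cycles(s, prot)
  last <- seg[200, ]
  expect_gt(s$strain[last$end], s$strain[last$start])
  # loop opening convention: at equal stress the loading branch lies above
  # the unloading branch in strain
  mid_load <- last$start + (last$peak - last$start) %/% 2L
  mid_unload <- last$peak + (last$end - last$peak) %/% 2L
  expect_equal(s$stress_MPa[mid_load], s$stress_MPa[mid_unload])
  expect_gt(s$strain[mid_load], s$strain[mid_unload])
})

test_that("per-cycle ratcheting strain equals injected drift plus elastic mean", {
  for (cond in list(c(1.76, 1.18), c(0.59, 0.59), c(0.88, 0.59))) {
    prot <- loading_protocol(cond[1], cond[2], n_cycles = 60)
    p <- clean_params()
    s <- generate_response(prot, p)
    curve <- build_ratcheting_curve(s, prot)
    drift <- discratchet:::drift_curve(p, prot)
    E <- discratchet:::effective_modulus(p, prot)
    expect_equal(curve$ratcheting_strain,
                 drift[1:60] + cond[1] / (2 * E), tolerance = 1e-6)
  }
})

test_that("monotone effect directions hold on noise-free specimens", {
  er400 <- function(dsig, rate, segf = 1) {
    prot <- loading_protocol(dsig, rate, n_cycles = 400)
    s <- generate_response(prot, clean_params(segment_factor = segf))
    cs <- cycle_summaries(s, prot, sheep_geometry())
    cs[400, c("ratcheting_strain", "stiffness_N_per_mm")]
  }
  # larger stress variation at fixed rate: more ratcheting, stiffer
  at_dsig <- lapply(c(0.59, 1.18, 1.76), er400, rate = 0.59)
  er <- sapply(at_dsig, `[[`, "ratcheting_strain")
  st <- sapply(at_dsig, `[[`, "stiffness_N_per_mm")
  expect_true(all(diff(er) > 0))
  expect_true(all(diff(st) > 0))
  # larger stress rate at fixed stress variation: less ratcheting, stiffer
  at_rate <- lapply(c(0.13, 0.4, 1.18), function(r) er400(0.59, r))
  er <- sapply(at_rate, `[[`, "ratcheting_strain")
  st <- sapply(at_rate, `[[`, "stiffness_N_per_mm")
  expect_true(all(diff(er) < 0))
  expect_true(all(diff(st) > 0))
  # segment factor < 1 scales the whole ratcheting curve down
  prot <- loading_protocol(1.18, 0.59, n_cycles = 50)
  c_l56 <- build_ratcheting_curve(generate_response(prot, clean_params()), prot)
  c_l67 <- build_ratcheting_curve(
    generate_response(prot, clean_params(segment_factor = 0.8)), prot)
  expect_true(all(c_l67$ratcheting_strain < c_l56$ratcheting_strain))
})

test_that("cohort generation tags conditions, respects jitter and seed", {
  conds <- standard_conditions(n_replicates = 3)
  expect_equal(nrow(conds), 10)
  coh <- generate_cohort(conds, n_cycles = 3, seed = 11)
  expect_length(coh, 30)
  expect_equal(attr(coh[[1]], "protocol")$stress_variation,
               conds$stress_variation[1])
  # zero jitter + zero noise: replicates of a condition are identical
  coh0 <- generate_cohort(conds[1:2, ], base_params = clean_params(),
                          n_cycles = 3, jitter_sdlog_modulus = 0,
                          jitter_sdlog_drift = 0, seed = 5)
  expect_identical(coh0[[1]]$strain, coh0[[2]]$strain)
  # same cohort seed twice: identical output sets
  cohA <- generate_cohort(conds[1:2, ], n_cycles = 3, seed = 9)
  cohB <- generate_cohort(conds[1:2, ], n_cycles = 3, seed = 9)
  expect_identical(lapply(cohA, as.data.frame), lapply(cohB, as.data.frame))
  expect_error(generate_cohort(conds[0, ]), "non-empty")
  conds$n_replicates <- 0L
  expect_error(generate_cohort(conds), "at least one replicate")
})
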