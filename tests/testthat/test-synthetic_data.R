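test_that("generate_ensemble: determinism, ranges, edge cases", {
  cfg <- ground_truth(d_mean = c(14, 20), d_sd = c(6, 8),
                      n_np = c(1e10, 2.4e10), seed = 77)
  expect_identical(generate_ensemble(cfg, 0), list())
  e1 <- generate_ensemble(cfg, 5)
  e2 <- generate_ensemble(cfg, 5)
  expect_identical(e1, e2)                     # same seed, same ensemble
  d_means <- vapply(e1, function(g) g$d_mean, 0)
  expect_true(all(d_means >= 14 & d_means <= 20))
  expect_gt(length(unique(d_means)), 1)

  # monodisperse configuration stays monodisperse
  gt0 <- ground_truth(d_mean = 15, d_sd = 0, n_np = 1e8, seed = 3)
  sim <- simulate_voltammograms(gt0)
  expect_true(all(sim$truth$diameters == 15))
})

test_that("simulated traces are reproducible bit-for-bit from the seed", {
  gt <- ground_truth(seed = 123)
  s1 <- simulate_voltammograms(gt)
  s2 <- simulate_voltammograms(gt)
  expect_identical(s1$oxide$current, s2$oxide$current)
  expect_identical(s1$stripping$current, s2$stripping$current)
  f1 <- simulate_fluorescence(gt, truth = s1$truth)
  f2 <- simulate_fluorescence(gt, truth = s2$truth)
  expect_identical(f1$standards$intensity, f2$standards$intensity)
  expect_identical(f1$sample$intensity, f2$sample$intensity)
})

test_that("zero particles give baseline-only traces and S ~ 0", {
  gt <- ground_truth(n_np = 0, noise = zero_noise(), seed = 5)
  sim <- simulate_voltammograms(gt)
  expect_true(all(sim$oxide$current == 0))
  q_ox <- integrate_charge(sim$oxide, oxide_window(), "linear_anchors")
  expect_equal(area_from_oxide_charge(q_ox$q), 0, tolerance = 1e-12)
})

test_that("noiseless monodisperse ensemble: pipeline recovers d and N", {
  gt <- ground_truth(d_mean = 16, d_sd = 0, n_np = 8e9,
                     noise = zero_noise(), seed = 21)
  sim <- simulate_voltammograms(gt)
  q_ox <- integrate_charge(sim$oxide, oxide_window())
  q_st <- integrate_charge(sim$stripping, stripping_window())
  np <- estimate_np(q_st$q, q_ox$q)
  expect_rel_equal(np$d, 16, 0.005)      # < 0.5%
  expect_rel_equal(np$n_np, 8e9, 0.01)   # < 1%
  # generator bookkeeping is the oracle for the integrated charges
  expect_rel_equal(q_ox$q, sim$truth$q_ox, 0.005)
  expect_rel_equal(q_st$q, sim$truth$q_strip, 0.005)
})

test_that("fluorescence simulation: blanks, exact round trip, footprint", {
  # density 0 -> sample at blank intensity
  gt0 <- ground_truth(enzyme_density = 0, noise = zero_noise(), seed = 2)
  f0 <- simulate_fluorescence(gt0)
  expect_equal(f0$sample$intensity, gt0$cal$intercept)

  # noiseless: pipeline count equals planted count to < 0.1%
  gt <- ground_truth(d_mean = 14, d_sd = 0, n_np = 1e10,
                     enzyme_density = 1.5 / hemisphere_area(14),
                     noise = zero_noise(), seed = 8)
  sim <- simulate_voltammograms(gt)
  flu <- simulate_fluorescence(gt, truth = sim$truth)
  curve <- fit_calibration(flu$standards)
  conc <- concentration_from_intensity(curve, flu$sample$intensity)$conc
  count <- enzyme_count(conc, gt$volume)
  expect_rel_equal(count, flu$truth$enzyme_count, 1e-3)

  # planted 1.5 enzymes/NP at d = 14 -> footprint ~ 205 nm2
  np <- estimate_np(integrate_charge(sim$stripping, stripping_window())$q,
                    integrate_charge(sim$oxide, oxide_window())$q)
  er <- per_np_and_footprint(count, np)
  expect_rel_equal(er$per_np, 1.5, 1e-3)
  expect_rel_equal(er$footprint, hemisphere_area(14) / 1.5, 1e-3)
})

test_that("default-noise recovery: per_np within 10% (seed median)", {
  # spec-scale study is 500 seeds; 60 seeds keep the suite fast
  errs <- vapply(1:60, function(s) {
    gt <- ground_truth(d_mean = 17, d_sd = 0, n_np = 1.9e10, seed = s)
    sim <- simulate_voltammograms(gt)
    flu <- simulate_fluorescence(gt, truth = sim$truth)
    np <- estimate_np(integrate_charge(sim$stripping, stripping_window())$q,
                      integrate_charge(sim$oxide, oxide_window())$q)
    conc <- concentration_from_intensity(fit_calibration(flu$standards),
                                         flu$sample$intensity)$conc
    er <- per_np_and_footprint(enzyme_count(conc, gt$volume), np)
    abs(er$per_np - flu$truth$enzyme_count / gt$n_np) * gt$n_np /
      flu$truth$enzyme_count
  }, 0)
  expect_lt(median(errs), 0.10)
})

test_that("generator and estimator are independent implementations", {
  # the generator's per-particle sums see polydispersity; the estimator's
  # mean-radius closed form does not -- at c = 0.2 the discrepancy in the
  # recovered diameter must match the analytic (1+3c^2)/(1+c^2) factor
  gt <- ground_truth(d_mean = 20, d_sd = 4, n_np = 1e10,
                     noise = zero_noise(), seed = 31)
  sim <- simulate_voltammograms(gt)
  np <- estimate_np(integrate_charge(sim$stripping, stripping_window())$q,
                    integrate_charge(sim$oxide, oxide_window())$q)
  d <- sim$truth$diameters
  expect_rel_equal(np$d, sum((d / 2)^3) / sum((d / 2)^2) * 2, 0.01)
  expect_gt(np$d, 20)  # charge-weighted mean exceeds the arithmetic mean
})
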