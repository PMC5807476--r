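test_that("calibration fit: noiseless line recovered exactly", {
  conc <- c(0, 1e-10, 2e-10, 4e-10)
  std <- data.frame(conc = conc, intensity = 2e9 * conc + 5)
  curve <- fit_calibration(std)
  expect_equal(curve$slope, 2e9)
  expect_equal(curve$intercept, 5)
  expect_equal(curve$r2, 1)
  expect_equal(curve$blank, 5)
  expect_equal(curve$n_points, 4)
  expect_true(curve$usable)
})

test_that("calibration fit: preconditions and negative-slope flag", {
  expect_error(fit_calibration(data.frame(conc = c(1e-10, 2e-10),
                                          intensity = c(1, 2))),
               "3 distinct")
  expect_error(fit_calibration(data.frame(conc = rep(1e-10, 5),
                                          intensity = 1:5)),
               "3 distinct")
  expect_warning(
    curve <- fit_calibration(data.frame(conc = c(1e-10, 2e-10, 3e-10),
                                        intensity = c(30, 20, 10))),
    "unusable")
  expect_false(curve$usable)
  expect_error(concentration_from_intensity(curve, 15), "unusable")
})

test_that("noisy calibration recovers the true slope (Monte Carlo)", {
  # spec-scale study is 500 seeds; 300 keeps the suite fast and the
  # 3-standard-error criterion is on the Monte-Carlo mean
  true_slope <- 3e11; true_int <- 4
  conc <- seq(5e-11, 4e-10, length.out = 8)
  set.seed(20)
  slopes <- replicate(300, {
    intensity <- (true_slope * conc + true_int) * (1 + rnorm(8, 0, 0.02))
    fit_calibration(data.frame(conc = conc, intensity = intensity))$slope
  })
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - true_slope), 3 * se + 1e-4 * true_slope)
})

test_that("inverse prediction is the algebraic inverse, with flags", {
  std <- data.frame(conc = c(1e-10, 2e-10, 3e-10, 4e-10))
  std$intensity <- 5e11 * std$conc + 3
  curve <- fit_calibration(std)
  # exact inverse on the line
  for (c0 in std$conc) {
    expect_equal(concentration_from_intensity(curve, 5e11 * c0 + 3)$conc, c0,
                 tolerance = 1e-9)
  }
  # intensity at the blank -> zero concentration
  expect_equal(concentration_from_intensity(curve, curve$intercept)$conc, 0)
  # below blank -> floored at 0 and flagged
  res <- concentration_from_intensity(curve, curve$intercept - 1)
  expect_equal(res$conc, 0)
  expect_true("negative_concentration" %in% res$flags)
  # 10% above the top standard -> extrapolation flag, value still returned
  hi <- 1.1 * max(std$intensity)
  res2 <- concentration_from_intensity(curve, hi)
  expect_true("extrapolation" %in% res2$flags)
  expect_gt(res2$conc, max(std$conc))
})

test_that("absolute count arithmetic", {
  expect_rel_equal(enzyme_count(1e-12, 200e-6), 1.2044e8, 1e-3)
  expect_equal(enzyme_count(0, 200e-6), 0)
  expect_equal(enzyme_count(3e-12, 400e-6), 2 * enzyme_count(3e-12, 200e-6))
  expect_error(enzyme_count(-1e-12, 200e-6), ">= 0")
  expect_error(enzyme_count(1e-12, 0), "> 0")
})

test_that("per-NP count and footprint are mutually consistent", {
  q_st <- stripping_charge_forward(7, 2e10)
  q_ox <- 489e-6 * 2 * pi * (7e-7)^2 * 2e10
  np <- estimate_np(q_st, q_ox)

  # count == n_np -> exactly one enzyme per particle, footprint = cap area
  er <- per_np_and_footprint(np$n_np, np)
  expect_equal(er$per_np, 1)
  expect_rel_equal(er$footprint, hemisphere_area(np$d), 1e-9)
  expect_false("footprint_routes_disagree" %in% er$flags)

  # footprint * per_np * n_np = total area in nm2, by construction
  er2 <- per_np_and_footprint(3.2e10, np, conc = 2.5e-10)
  expect_rel_equal(er2$footprint * er2$per_np * np$n_np,
                   np$s_total * 1e14, 1e-9)

  # degenerate inputs
  er0 <- per_np_and_footprint(0, np)
  expect_equal(er0$per_np, 0)
  expect_true(is.na(er0$footprint))
  expect_true("zero_enzyme_count" %in% er0$flags)
  np0 <- np; np0$n_np <- 0
  expect_error(per_np_and_footprint(10, np0), "> 0")
})

test_that("degree of labeling inverts constructed absorbances", {
  eps_d <- 71000; eps_p <- 267200; cf <- 0.11
  # plant a concentration and DOL, construct the absorbances, invert
  conc0 <- 5e-6; dol0 <- 3.2
  a_dye <- dol0 * conc0 * eps_d
  a_280 <- conc0 * eps_p + cf * a_dye
  res <- degree_of_labeling(a_dye, a_280, eps_d, eps_p, cf)
  expect_equal(res$protein_conc, conc0, tolerance = 1e-12)
  expect_equal(res$dol, dol0, tolerance = 1e-12)

  # no dye: DOL 0 and plain Beer-Lambert
  res0 <- degree_of_labeling(0, 0.5, eps_d, eps_p, cf)
  expect_equal(res0$dol, 0)
  expect_equal(res0$protein_conc, 0.5 / eps_p)
  # cf = 0 reduces to the uncorrected form
  res1 <- degree_of_labeling(a_dye, a_280, eps_d, eps_p, 0)
  expect_equal(res1$protein_conc, a_280 / eps_p)
  # over-correction rejected
  expect_error(degree_of_labeling(10, 0.5, eps_d, eps_p, 1), "corrected A280")
})
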