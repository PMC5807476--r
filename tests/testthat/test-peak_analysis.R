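test_that("baseline subtraction recovers a planted Gaussian on a linear ramp", {
  h <- 5e-6; sigma <- 0.03; mu <- 1.2
  ramp <- function(E) 2e-6 + 4e-6 * (E - 1.0)
  v <- make_gaussian_sweep(h, mu, sigma, e_range = c(0.9, 1.5),
                           baseline = ramp)
  w <- peak_window(mu - 5 * sigma, mu + 5 * sigma, "anodic")
  ct <- subtract_baseline(v, w, "linear_anchors")
  cc <- ct$cycles[[1]]
  truth <- h * exp(-(cc$potential - mu)^2 / (2 * sigma^2))
  expect_true(all(abs(cc$corrected - truth) < 0.01 * h))
  expect_named(cc$anchors, c("low", "high"))

  # a trace that IS a straight line corrects to ~0 everywhere
  v0 <- voltammogram(seq(0.9, 1.5, 0.001), ramp(seq(0.9, 1.5, 0.001)), 0.1)
  ct0 <- subtract_baseline(v0, w, "linear_anchors")
  expect_true(all(abs(ct0$cycles[[1]]$corrected) < 1e-18))

  # flat method on a zero-current trace stays zero
  vz <- voltammogram(seq(0.9, 1.5, 0.001), rep(0, 601), 0.1)
  expect_true(all(subtract_baseline(vz, w, "flat")$cycles[[1]]$corrected == 0))
})

test_that("integrate_charge matches the closed-form Gaussian charge", {
  A <- 2e-5; sigma <- 0.035; mu <- 1.3; nu <- 0.1
  v <- make_gaussian_sweep(A, mu, sigma, scan_rate = nu,
                           e_range = c(0.9, 1.7), step = 1e-3)
  w <- peak_window(mu - 5 * sigma, mu + 5 * sigma, "anodic")
  res <- integrate_charge(v, w, "flat")
  exact <- gaussian_charge_exact(A, mu, sigma, nu, w$e_start, w$e_end)
  expect_rel_equal(res$q, exact, 5e-3)
  expect_rel_equal(res$q, A * sigma * sqrt(2 * pi) / nu, 5e-3)
  expect_equal(res$e_peak, mu, tolerance = 1e-2)
  expect_equal(res$q, sum(res$per_cycle))

  # zero current integrates to zero charge
  vz <- voltammogram(seq(0.9, 1.5, 0.001), rep(0, 601), 0.1)
  expect_equal(integrate_charge(vz, w, "flat")$q, 0)
})

test_that("direction filter: only the stated sweep direction contributes", {
  # CV with an anodic peak on the forward sweep only; the cathodic return
  # carries a mirrored peak that must NOT enter an anodic integration
  E <- triangular_potential(1, 0.9, 1.5, 0.001)
  dirs <- c(rep(1, 601), rep(-1, 600))
  peak <- 1e-5 * exp(-(E - 1.3)^2 / (2 * 0.03^2))
  i <- ifelse(dirs > 0, peak, -peak)
  v <- voltammogram(E, i, 0.1)
  q_an <- integrate_charge(v, peak_window(1.1, 1.5, "anodic"), "flat")$q
  q_ca <- integrate_charge(v, peak_window(1.1, 1.5, "cathodic"), "flat")$q
  exact <- gaussian_charge_exact(1e-5, 1.3, 0.03, 0.1, 1.1, 1.5)
  expect_rel_equal(q_an, exact, 5e-3)
  expect_rel_equal(q_ca, exact, 5e-3)  # each direction counted once only
})

test_that("multi-cycle stripping: nearly all charge lands in cycle 1", {
  gt <- ground_truth(d_mean = 17, d_sd = 0, n_np = 1e10,
                     noise = zero_noise(), seed = 3)
  sim <- simulate_voltammograms(gt)
  res <- integrate_charge(sim$stripping, stripping_window(), "linear_anchors")
  expect_length(res$per_cycle, 6)
  expect_gt(res$per_cycle[1], 0.99 * res$q)
  expect_true(all(res$per_cycle[-1] < 0.01 * res$q))
})

test_that("charge invariances: potential shift, amplitude, scan rate, window", {
  A <- 1e-5; sigma <- 0.03; mu <- 1.25; nu <- 0.1
  base <- function(E) 1e-6 + 2e-6 * E
  v <- make_gaussian_sweep(A, mu, sigma, nu, c(0.9, 1.6), 1e-3, baseline = base)
  w <- peak_window(mu - 5 * sigma, mu + 5 * sigma, "anodic")
  q0 <- integrate_charge(v, w)$q

  # uniform potential shift of trace + window
  v_sh <- voltammogram(v$potential + 0.2, v$current, nu)
  w_sh <- peak_window(w$e_start + 0.2, w$e_end + 0.2, "anodic")
  expect_rel_equal(integrate_charge(v_sh, w_sh)$q, q0, 1e-9)

  # linear in amplitude (baseline-corrected), exact for the trapezoid
  v2 <- make_gaussian_sweep(2 * A, mu, sigma, nu, c(0.9, 1.6), 1e-3,
                            baseline = base)
  expect_rel_equal(integrate_charge(v2, w)$q, 2 * q0, 1e-9)

  # inverse in scan rate
  v3 <- make_gaussian_sweep(A, mu, sigma, 2 * nu, c(0.9, 1.6), 1e-3,
                            baseline = base)
  expect_rel_equal(integrate_charge(v3, w)$q, q0 / 2, 1e-9)

  # growing a window that already contains the peak changes q by < 1%
  w_big <- peak_window(mu - 7 * sigma, mu + 7 * sigma, "anodic")
  expect_rel_equal(integrate_charge(v, w_big)$q, q0, 1e-2)
})

test_that("window and resolution errors are reported", {
  v <- voltammogram(seq(0.9, 1.5, 0.01), rep(1e-6, 61), 0.1)
  expect_error(integrate_charge(v, peak_window(2.0, 2.5, "anodic")),
               "outside the sweep range")
  expect_error(integrate_charge(v, peak_window(1.2, 1.21, "anodic")),
               "resolution")
  expect_error(integrate_charge(v, peak_window(1.1, 1.4, "cathodic")),
               "direction")
  v$scan_rate <- 0
  expect_error(integrate_charge(v, peak_window(1.1, 1.4, "anodic")),
               "scan_rate")
})
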