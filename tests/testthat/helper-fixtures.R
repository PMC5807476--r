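# Shared fixtures: analytic voltammograms and closed-form charge oracles.

# Single linear sweep carrying a Gaussian current peak on an arbitrary
# baseline.  `direction` +1 sweeps low->high, -1 high->low.
make_gaussian_sweep <- function(amp, center, sigma, scan_rate = 0.1,
                                e_range = c(center - 6 * sigma,
                                            center + 6 * sigma),
                                step = sigma / 50, direction = 1,
                                baseline = function(E) 0) {
  E <- seq(e_range[1], e_range[2], by = step)
  if (direction < 0) E <- rev(E)
  i <- amp * exp(-(E - center)^2 / (2 * sigma^2)) + baseline(E)
  if (direction < 0) i <- -i   # cathodic peaks are negative currents
  voltammogram(E, i, scan_rate)
}

# Closed-form |charge| of a Gaussian peak integrated over [a, b]:
# (A / nu) * integral exp(-(E-mu)^2/(2 sigma^2)) dE, via the normal CDF.
gaussian_charge_exact <- function(amp, center, sigma, scan_rate, a, b) {
  amp * sigma * sqrt(2 * pi) / scan_rate *
    (stats::pnorm((b - center) / sigma) - stats::pnorm((a - center) / sigma))
}

# Triangular potential program of k full cycles.
triangular_potential <- function(k, lo = 0.9, hi = 1.5, step = 0.01) {
  up <- seq(lo, hi, by = step)
  down <- seq(hi - step, lo, by = -step)
  rep(c(up, down), k)
}

nm_to_cm_test <- function(x) x * 1e-7

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual - expected) <= rel_tol * abs(expected)),
              label = sprintf("%s within %g of %s",
                              paste(signif(actual, 6), collapse = ","),
                              rel_tol,
                              paste(signif(expected, 6), collapse = ",")))
}
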