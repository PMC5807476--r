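#' Ground-truth configuration for the forward simulator
#'
#' States the world that the simulator emulates: a hemispherical gold
#' nanoparticle ensemble with an approximately Gaussian diameter distribution
#' (truncated at 0), enzymes adsorbed at a fixed surface density, and the
#' instrument's noise floor.  Defaults mirror the scale of electrodeposited
#' AuNP ensembles on a 3-mm glassy carbon disc: mean diameter 17 nm, SD 7 nm,
#' 1.9e10 particles, and roughly monolayer enzyme coverage.
#'
#' @param d_mean Mean particle diameter, nm; a length-2 vector is a range
#'   sampled uniformly per electrode by [generate_ensemble()].
#' @param d_sd Within-electrode diameter SD, nm (or range).
#' @param n_np Number of particles per electrode (or range).
#' @param enzyme_density Enzymes per nm2 of nanoparticle surface (or range).
#'   The default corresponds to ~1.5 enzymes on a 14-nm hemisphere.
#' @param electrode_diameter Disc diameter, mm.
#' @param noise List of instrument-noise settings:
#'   `current_rms` (A, Gaussian white noise on every current sample),
#'   `baseline_i0` (A, capacitive baseline magnitude),
#'   `baseline_slope` (A/V), `baseline_curvature` (A/V2),
#'   `fluorescence_cv` (relative, multiplicative on intensities).
#' @param cal True fluorescence calibration: list `slope` (intensity per
#'   mol/L) and `intercept` (blank intensity).
#' @param volume Stripping solution volume, L.
#' @param seed Integer seed recorded in every output header.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(d_mean = 17, d_sd = 7, n_np = 1.9e10,
                         enzyme_density = 1.5 / hemisphere_area(14),
                         electrode_diameter = 3,
                         noise = default_noise(),
                         cal = list(slope = 1e12, intercept = 2),
                         volume = 200e-6, seed = 1L) {
  stopifnot(all(d_mean > 0), all(d_sd >= 0), all(n_np >= 0),
            all(enzyme_density >= 0), electrode_diameter > 0, volume > 0)
  noise <- utils::modifyList(default_noise(), as.list(noise))
  structure(list(d_mean = d_mean, d_sd = d_sd, n_np = n_np,
                 enzyme_density = enzyme_density,
                 electrode_diameter = electrode_diameter, noise = noise,
                 cal = cal, volume = volume, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Default instrument-noise settings
#'
#' Realistic for microampere-scale peaks on a 3-mm disc at 0.1 V/s: 0.2 uA
#' RMS current noise, ~2 uA capacitive baseline with mild slope and
#' curvature, and 2% fluorescence reading CV.
#' @return Named list of noise settings.
#' @export
default_noise <- function() {
  list(current_rms = 2e-7, baseline_i0 = 2e-6, baseline_slope = 3e-6,
       baseline_curvature = 1e-6, fluorescence_cv = 0.02)
}

#' Zero-noise settings (deterministic, baseline-free traces)
#' @return Named list of noise settings, all zero.
#' @export
zero_noise <- function() {
  list(current_rms = 0, baseline_i0 = 0, baseline_slope = 0,
       baseline_curvature = 0, fluorescence_cv = 0)
}

draw_in_range <- function(x) {
  if (length(x) == 2 && x[2] > x[1]) stats::runif(1, x[1], x[2]) else x[1]
}

#' Draw per-electrode ground truths from a configuration
#'
#' Range-valued fields of the configuration are sampled uniformly per
#' electrode; scalar fields are copied.  Reproducible given the seed.
#'
#' @param config A [ground_truth()] (fields may be length-2 ranges).
#' @param n_electrodes Number of electrodes (>= 0).
#' @return List of scalar-field `ground_truth` objects, one per electrode,
#'   each with its own derived seed.
#' @export
generate_ensemble <- function(config, n_electrodes) {
  stopifnot(inherits(config, "ground_truth"), n_electrodes >= 0)
  if (n_electrodes == 0) return(list())
  out <- vector("list", n_electrodes)
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_electrodes)
  for (i in seq_len(n_electrodes)) {
    out[[i]] <- ground_truth(
      d_mean = draw_in_range(config$d_mean),
      d_sd = draw_in_range(config$d_sd),
      n_np = draw_in_range(config$n_np),
      enzyme_density = draw_in_range(config$enzyme_density),
      electrode_diameter = config$electrode_diameter,
      noise = config$noise, cal = config$cal, volume = config$volume,
      seed = sub_seeds[i])
  }
  out
}

# Draw the particle population of one electrode and do the per-particle
# (atom-sum) bookkeeping.  Populations beyond `max_draw` particles are
# represented by a scaled subsample: m drawn diameters stand for n_np/m
# particles each.  This stays a per-particle summation route, independent of
# the estimator's mean-radius closed form.
sample_population <- function(gt, max_draw = 2e4) {
  m <- min(gt$n_np, max_draw)
  m_int <- max(1L, as.integer(round(m)))
  if (gt$n_np == 0) {
    return(list(d = numeric(0), weight = 0, s_total = 0, q_strip = 0,
                q_ox = 0, d_cw = NA_real_))
  }
  if (gt$d_sd == 0) {
    d <- rep(gt$d_mean, m_int)
  } else {
    d <- stats::rnorm(m_int, gt$d_mean, gt$d_sd)
    while (any(d <= 0)) {  # truncate at > 0
      bad <- d <= 0
      d[bad] <- stats::rnorm(sum(bad), gt$d_mean, gt$d_sd)
    }
  }
  w <- gt$n_np / m_int
  r <- d / 2
  s_total <- w * sum(2 * pi * nm_to_cm(r)^2)           # cm2, curved caps
  consts <- stripping_constants()
  q_strip <- stripping_charge_forward(r, rep(w, m_int), consts)
  q_ox <- consts$k_ox * s_total
  list(d = d, weight = w, s_total = s_total, q_strip = q_strip, q_ox = q_ox,
       d_cw = 2 * sum(r^3) / sum(r^2))
}

gaussian_peak <- function(E, center, sigma, q, scan_rate) {
  # a peak of total |charge| q: amplitude = q * nu / (sigma * sqrt(2*pi))
  a <- q * scan_rate / (sigma * sqrt(2 * pi))
  a * exp(-(E - center)^2 / (2 * sigma^2))
}

capacitive_baseline <- function(E, direction, noise, e_ref = 1.2) {
  sgn <- ifelse(direction >= 0, 1, -1)
  sgn * (noise$baseline_i0 + noise$baseline_slope * (E - e_ref) +
           noise$baseline_curvature * (E - e_ref)^2)
}

#' Forward-simulate the two voltammograms of one electrode
#'
#' Produces (1) the oxide-reduction linear sweep, +1.7 V down to +0.8 V vs
#' NHE, with the cathodic gold-oxide reduction peak at +1.1 V (sigma 40 mV)
#' carrying charge `k_ox * S*`, and (2) the 6-cycle stripping CV, +0.9 to
#' +1.5 V, with the anodic gold dissolution peak at +1.3 V (sigma 35 mV)
#' carrying the per-particle-summed stripping charge, >= 99% of it in cycle
#' 1 and the remainder in cycle 2.  Both ride on a capacitive baseline
#' (sign-following, linear plus mild curvature) with Gaussian current noise,
#' sampled at 1 mV.
#'
#' `S*` is the per-particle sum of curved hemisphere areas — the generator
#' never uses the estimator's mean-radius closed form.
#'
#' @param gt A scalar-field [ground_truth()].
#' @param scan_rate Scan rate, V/s.
#' @param step Potential step, V (default 1 mV).
#' @param residual_fraction Fraction of the stripping charge left to cycle 2
#'   (default 0.005, i.e. 99.5% stripped in cycle 1).
#' @return List with voltammograms `oxide` and `stripping`, and `truth`: the
#'   realized bookkeeping (`s_total` cm2, `q_strip`, `q_ox` C, `d_cw` the
#'   charge-weighted mean diameter nm, `n_np`, `enzyme_count`, per-particle
#'   diameters of the (possibly scaled) subsample).
#' @export
simulate_voltammograms <- function(gt, scan_rate = 0.1, step = 1e-3,
                                   residual_fraction = 0.005) {
  stopifnot(inherits(gt, "ground_truth"))
  set.seed(gt$seed)
  pop <- sample_population(gt)

  # oxide-reduction LSV: 1.7 -> 0.8 V, cathodic
  E_ox <- seq(1.7, 0.8, by = -step)
  i_ox <- -gaussian_peak(E_ox, 1.1, 0.040, pop$q_ox, scan_rate) +
    capacitive_baseline(E_ox, -1, gt$noise) +
    stats::rnorm(length(E_ox), 0, gt$noise$current_rms)
  v_ox <- voltammogram(E_ox, i_ox, scan_rate, reference = "NHE",
                       meta = list(kind = "oxide_reduction_lsv",
                                   seed = gt$seed))

  # stripping CV: 6 triangular cycles 0.9 -> 1.5 -> 0.9 V
  up <- seq(0.9, 1.5, by = step)
  down <- seq(1.5 - step, 0.9, by = -step)
  n_cycles <- 6L
  E_st <- rep(c(up, down), n_cycles)
  dirs <- rep(rep(c(1, -1), n_cycles), times = rep(c(length(up), length(down)),
                                                   n_cycles))
  cyc_id <- rep(seq_len(n_cycles), each = length(up) + length(down))
  q_cycle <- c(pop$q_strip * (1 - residual_fraction),
               pop$q_strip * residual_fraction, rep(0, n_cycles - 2))
  i_st <- capacitive_baseline(E_st, dirs, gt$noise) +
    stats::rnorm(length(E_st), 0, gt$noise$current_rms)
  for (k in seq_len(n_cycles)) {
    sel <- cyc_id == k & dirs > 0
    i_st[sel] <- i_st[sel] +
      gaussian_peak(E_st[sel], 1.3, 0.035, q_cycle[k], scan_rate)
  }
  v_st <- voltammogram(E_st, i_st, scan_rate, reference = "NHE",
                       meta = list(kind = "stripping_cv", seed = gt$seed))

  n_enz <- gt$enzyme_density * cm2_to_nm2(pop$s_total)
  list(oxide = v_ox, stripping = v_st,
       truth = list(s_total = pop$s_total, q_strip = pop$q_strip,
                    q_ox = pop$q_ox, d_cw = pop$d_cw, n_np = gt$n_np,
                    d_mean = gt$d_mean, d_sd = gt$d_sd,
                    enzyme_count = n_enz, diameters = pop$d,
                    weight = pop$weight))
}

#' Forward-simulate the fluorescence readings of one electrode
#'
#' The planted enzyme count is `density * S*` (S* in nm2); the sample
#' intensity follows the true linear calibration with multiplicative noise
#' of the configured CV.  Standards (>= 5 points, plus a blank) span twice
#' the sample concentration.
#'
#' @param gt A scalar-field [ground_truth()].
#' @param truth Bookkeeping from [simulate_voltammograms()] for the same
#'   electrode (used for `S*`); when `NULL` the population is redrawn from
#'   the seed.
#' @param n_standards Number of non-blank standards.
#' @return List with `standards` (data.frame `id, conc, intensity`),
#'   `sample` (list `intensity, volume`), and `truth` (`enzyme_count`,
#'   `conc`).
#' @export
simulate_fluorescence <- function(gt, truth = NULL, n_standards = 5) {
  stopifnot(inherits(gt, "ground_truth"))
  if (is.null(truth)) {
    set.seed(gt$seed)
    pop <- sample_population(gt)
    truth <- list(s_total = pop$s_total,
                  enzyme_count = gt$enzyme_density * cm2_to_nm2(pop$s_total))
  }
  set.seed(gt$seed + 1L)
  count <- truth$enzyme_count
  conc <- count / (6.02214076e23 * gt$volume)
  conc_max <- if (conc > 0) 2 * conc else 1e-9
  conc_std <- c(0, seq(conc_max / n_standards, conc_max,
                       length.out = n_standards))
  cv <- gt$noise$fluorescence_cv
  noise_fac <- function(n) if (cv > 0) 1 + stats::rnorm(n, 0, cv) else rep(1, n)
  i_std <- (gt$cal$slope * conc_std + gt$cal$intercept) * noise_fac(length(conc_std))
  i_sample <- (gt$cal$slope * conc + gt$cal$intercept) * noise_fac(1)
  list(standards = data.frame(id = seq_along(conc_std), conc = conc_std,
                              intensity = i_std),
       sample = list(intensity = i_sample, volume = gt$volume),
       truth = list(enzyme_count = count, conc = conc))
}
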