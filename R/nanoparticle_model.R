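#' Total nanoparticle surface area from the gold-oxide reduction charge
#'
#' The charge under the cathodic gold-oxide reduction peak is proportional to
#' the real gold surface area through the coulometric coefficient `k_ox`:
#' `S = q_ox / k_ox`.
#'
#' @param q_ox Integrated oxide-reduction charge, C (>= 0).
#' @param constants A [stripping_constants()] object.
#' @return Total nanoparticle surface area, cm2.
#' @export
area_from_oxide_charge <- function(q_ox, constants = stripping_constants()) {
  if (any(q_ox < 0)) stop("q_ox must be >= 0", call. = FALSE)
  q_ox / constants$k_ox
}

#' Mean nanoparticle radius from stripping and oxide charges
#'
#' The anodic stripping charge counts gold atoms (volume-proportional) while
#' the oxide-reduction charge measures surface area, so their ratio fixes a
#' mean radius:
#' `r = 3 M_Au / (n_eff e rho_Au N_A) * (Q/S)`, independent of the shape
#' factor.  Under a polydisperse population this is the charge-weighted mean
#' `<r^3>/<r^2>`, not the arithmetic mean (see the methods vignette).
#'
#' @param q_strip Integrated anodic stripping charge, C (> 0).
#' @param s_total Total nanoparticle surface area, cm2 (> 0).
#' @inheritParams area_from_oxide_charge
#' @return Mean radius in nm.
#' @export
radius_from_charges <- function(q_strip, s_total,
                                constants = stripping_constants()) {
  if (any(q_strip <= 0)) stop("q_strip must be > 0", call. = FALSE)
  if (any(s_total <= 0)) stop("s_total must be > 0", call. = FALSE)
  c_ <- constants
  r_cm <- (3 * c_$M_Au) / (c_$n_eff * c_$e * c_$rho_Au * c_$N_A) *
    (q_strip / s_total)
  cm_to_nm(r_cm)
}

#' Nanoparticle count from total area and mean radius
#'
#' Inverts the area bookkeeping `S = x pi r^2 N`.  The count is an ensemble
#' estimate and is deliberately not rounded to an integer.
#'
#' @param s_total Total nanoparticle surface area, cm2 (>= 0).
#' @param r Mean radius, nm (> 0).
#' @inheritParams area_from_oxide_charge
#' @return Number of nanoparticles (dimensionless, possibly non-integer).
#' @export
count_from_area <- function(s_total, r, constants = stripping_constants()) {
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  if (any(s_total < 0)) stop("s_total must be >= 0", call. = FALSE)
  s_total / (constants$x * pi * nm_to_cm(r)^2)
}

#' Forward model: stripping charge of a nanoparticle ensemble
#'
#' The charge released by completely stripping N particles of radius r:
#' `Q = n_eff * e * (x/3 pi r^3 rho_Au / M_Au) * N_A * N`.
#' This is the simulator-side inverse of [radius_from_charges()] +
#' [count_from_area()].
#'
#' @param r Particle radius, nm (scalar or vector; a vector is treated as a
#'   population and summed).
#' @param n_np Number of particles; with vector `r`, a per-particle weight
#'   (use 1 for an explicit population).
#' @inheritParams area_from_oxide_charge
#' @return Total stripping charge, C.
#' @export
stripping_charge_forward <- function(r, n_np,
                                     constants = stripping_constants()) {
  if (any(r < 0) || any(n_np < 0)) stop("r and n_np must be >= 0", call. = FALSE)
  c_ <- constants
  atoms <- (c_$x / 3) * pi * nm_to_cm(r)^3 * c_$rho_Au / c_$M_Au * c_$N_A
  sum(c_$n_eff * c_$e * atoms * n_np)
}

#' Projected surface coverage of the electrode by nanoparticles
#'
#' Percentage of the electrode's geometric disc area occupied by the projected
#' (footprint) area of the hemispherical particles, `100 pi r^2 N / A_geom`.
#' Values above 100% are possible for overlapping/multilayered deposits and
#' are flagged with a warning rather than rejected.
#'
#' @param r Mean particle radius, nm.
#' @param n_np Number of particles.
#' @param electrode_diameter Working-electrode disc diameter, mm (default 3).
#' @return Coverage, percent.
#' @export
coverage <- function(r, n_np, electrode_diameter = 3) {
  if (electrode_diameter <= 0) stop("electrode_diameter must be > 0", call. = FALSE)
  a_geom <- pi * (mm_to_cm(electrode_diameter) / 2)^2
  cov <- 100 * pi * nm_to_cm(r)^2 * n_np / a_geom
  if (any(cov > 100)) {
    warning("coverage exceeds 100% (overlapping or multilayer deposit?)",
            call. = FALSE)
  }
  cov
}

#' Curved surface area of a hemispherical nanoparticle
#'
#' `2 pi (d/2)^2`: the curved cap only, since the flat face rests on the
#' electrode and is unavailable for enzyme adsorption.
#'
#' @param d Particle diameter, nm (>= 0).
#' @return Surface area, nm2.
#' @examples
#' hemisphere_area(14)  # ~308 nm2, "about 300" at one significant figure
#' @export
hemisphere_area <- function(d) {
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  2 * pi * (d / 2)^2
}

#' Maximum number of enzymes packing onto a given surface area
#'
#' Simple area arithmetic: `area / footprint`, converted to a whole number of
#' enzymes.  Both rounding conventions are exposed because dense-packing
#' estimates in the literature use either: `round` gives the nearest integer
#' (15 enzymes on a 14-nm hemisphere at the 21 nm2 short-side footprint),
#' `floor` the guaranteed-to-fit count (4 at the 67 nm2 long-side footprint).
#'
#' @param area Available surface area, nm2 (>= 0).
#' @param footprint Area occupied by one enzyme, nm2 (> 0).  Glucose oxidase:
#'   21 nm2 short side, 67 nm2 long side, up to ~290 nm2 fully collapsed.
#' @param mode `"round"` or `"floor"`.
#' @return Integer number of enzymes.
#' @export
enzyme_packing <- function(area, footprint, mode = c("round", "floor")) {
  mode <- match.arg(mode)
  if (any(footprint <= 0)) stop("footprint must be > 0", call. = FALSE)
  if (any(area < 0)) stop("area must be >= 0", call. = FALSE)
  n <- area / footprint
  if (mode == "round") round(n) else floor(n)
}

#' Per-electrode nanoparticle estimate from the two charges
#'
#' Runs the full charge-to-geometry inversion: total area from the oxide
#' charge, mean radius from the charge ratio, particle count from the area
#' bookkeeping, and projected coverage of the electrode disc.
#'
#' @param q_strip Anodic stripping charge, C.
#' @param q_ox Gold-oxide reduction charge, C.
#' @param electrode_diameter Electrode disc diameter, mm.
#' @inheritParams area_from_oxide_charge
#' @return An `np_estimate` object: list with `r` and `d` (nm), `n_np`,
#'   `s_total` (cm2), `coverage` (%), `a_geom` (cm2) and the input charges.
#' @export
estimate_np <- function(q_strip, q_ox, electrode_diameter = 3,
                        constants = stripping_constants()) {
  s_total <- area_from_oxide_charge(q_ox, constants)
  r <- radius_from_charges(q_strip, s_total, constants)
  n_np <- count_from_area(s_total, r, constants)
  cov <- coverage(r, n_np, electrode_diameter)
  structure(list(
    r = r, d = 2 * r, n_np = n_np, s_total = s_total, coverage = cov,
    a_geom = pi * (mm_to_cm(electrode_diameter) / 2)^2,
    electrode_diameter = electrode_diameter,
    q_strip = q_strip, q_ox = q_ox, constants = constants
  ), class = "np_estimate")
}

#' @export
print.np_estimate <- function(x, ...) {
  cat("Nanoparticle estimate (per electrode):\n")
  cat(sprintf("  mean diameter : %.3g nm\n", x$d))
  cat(sprintf("  particle count: %.3g (%.2g x 1e9)\n", x$n_np, x$n_np / 1e9))
  cat(sprintf("  total NP area : %.3g cm2 (%.2g x 1e-2)\n",
              x$s_total, x$s_total / 1e-2))
  cat(sprintf("  coverage      : %.3g %% of a %.3g mm disc\n",
              x$coverage, x$electrode_diameter))
  cat(sprintf("  charges       : Q_strip = %.3g C, Q_ox = %.3g C\n",
              x$q_strip, x$q_ox))
  invisible(x)
}
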