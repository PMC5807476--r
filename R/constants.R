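#' Physical and coulometric constants for gold-nanoparticle stripping analysis
#'
#' Bundles every constant entering the charge-to-geometry conversions: the
#' coulometric coefficient relating gold-oxide reduction charge to real gold
#' surface area, the mean number of electrons transferred per gold atom during
#' anodic dissolution in chloride media, the particle shape factor, and the
#' physical constants for gold.
#'
#' Internally all arithmetic is done in CGS-consistent units (cm, g, C);
#' nanometre conversions happen only at the reporting boundary.
#'
#' @param k_ox Coulometric coefficient in C/cm2 of real gold surface: the
#'   charge required to reduce a monolayer of divalent oxide on polycrystalline
#'   gold.  Four literature values are in circulation (400, 450, 489 and
#'   543 uC/cm2); the default is 489e-6 C/cm2, appropriate for
#'   electrodeposited nanoparticles.  May also be given by name, see
#'   [k_ox_value()].  Any other value is accepted with a warning.
#' @param n_eff Mean electrons transferred per gold atom during stripping
#'   (dimensionless).  Default 1.9, reflecting the AuCl4-/AuCl2- equilibrium
#'   mixture produced by anodic dissolution in chloride.
#' @param x Particle shape factor: 2 for hemispheres sitting flat-face-down on
#'   the electrode (the default and the geometry assumed throughout), 3 for
#'   full spheres.
#' @param e Elementary charge, C.
#' @param N_A Avogadro constant, 1/mol.
#' @param rho_Au Density of gold, g/cm3.
#' @param M_Au Molar mass of gold, g/mol.
#' @return An object of class `stripping_constants` (a named list).
#' @examples
#' stripping_constants()                 # defaults
#' stripping_constants(k_ox = "trasatti")  # 400 uC/cm2 by name
#' @export
stripping_constants <- function(k_ox = 489e-6, n_eff = 1.9, x = 2,
                                e = 1.602176634e-19, N_A = 6.02214076e23,
                                rho_Au = 19.3, M_Au = 196.97) {
  if (is.character(k_ox)) k_ox <- k_ox_value(k_ox)
  stopifnot(k_ox > 0, n_eff > 0, x > 0, e > 0, N_A > 0, rho_Au > 0, M_Au > 0)
  known <- c(400e-6, 450e-6, 489e-6, 543e-6)
  if (!any(abs(k_ox - known) < 1e-12)) {
    warning(sprintf(
      "k_ox = %.4g C/cm2 is not one of the literature values (400/450/489/543 uC/cm2)",
      k_ox), call. = FALSE)
  }
  structure(list(k_ox = k_ox, n_eff = n_eff, x = x, e = e, N_A = N_A,
                 rho_Au = rho_Au, M_Au = M_Au),
            class = "stripping_constants")
}

#' Look up a coulometric coefficient by literature name
#'
#' @param name One of `"finot"` (489 uC/cm2, electrodeposited AuNP),
#'   `"habrioux"` (543), `"trasatti"` (400), `"tan"` (450), or the numeric
#'   value in uC/cm2 as a string (`"489"` etc.).
#' @return The coefficient in C/cm2.
#' @export
k_ox_value <- function(name) {
  tab <- c(finot = 489e-6, habrioux = 543e-6, trasatti = 400e-6, tan = 450e-6,
           "400" = 400e-6, "450" = 450e-6, "489" = 489e-6, "543" = 543e-6)
  key <- tolower(name)
  if (!key %in% names(tab)) {
    stop("unknown coulometric coefficient name: ", name,
         " (known: finot/habrioux/trasatti/tan or 400/450/489/543)",
         call. = FALSE)
  }
  unname(tab[key])
}

#' @export
print.stripping_constants <- function(x, ...) {
  cat("Stripping constants:\n")
  cat(sprintf("  k_ox   = %.4g C/cm2 (%.0f uC/cm2)\n", x$k_ox, x$k_ox * 1e6))
  cat(sprintf("  n_eff  = %.3g e-/Au atom\n", x$n_eff))
  cat(sprintf("  x      = %g (shape factor; 2 = hemisphere)\n", x$x))
  cat(sprintf("  rho_Au = %.3g g/cm3, M_Au = %.5g g/mol\n", x$rho_Au, x$M_Au))
  invisible(x)
}

# unit helpers -- conversions are kept explicit and local
nm_to_cm <- function(x) x * 1e-7
cm_to_nm <- function(x) x * 1e7
cm2_to_nm2 <- function(x) x * 1e14
mm_to_cm <- function(x) x * 0.1
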