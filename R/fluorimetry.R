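#' Fit a linear fluorescence calibration curve
#'
#' Ordinary least squares of intensity on concentration:
#' `intensity = slope * conc + intercept`.  The intercept doubles as the
#' blank.  A weighted fit (`weights`) and a through-blank fit
#' (`force_blank`, subtracts a measured blank and drops the intercept) are
#' available by configuration.
#'
#' @param standards A data.frame with columns `conc` (mol/L) and `intensity`
#'   (arbitrary units), or a two-column matrix/list in that order.  At least
#'   3 distinct concentrations are required.
#' @param weights Optional per-point weights for weighted least squares.
#' @param force_blank Optional measured blank intensity; when given, the fit
#'   is `intensity - blank = slope * conc` through the origin.
#' @return A `calibration_curve`: slope (intensity per mol/L), intercept,
#'   `r2`, `n_points`, `conc_range`, `intensity_range`, `blank`, `usable`.
#'   A non-positive slope flags the curve unusable with a warning.
#' @export
fit_calibration <- function(standards, weights = NULL, force_blank = NULL) {
  standards <- as.data.frame(standards)
  nm <- names(standards)
  conc_col <- intersect(c("conc", "conc_mol_per_L"), nm)[1]
  if (is.na(conc_col)) conc_col <- nm[1]
  int_col <- intersect(c("intensity"), nm)[1]
  if (is.na(int_col)) int_col <- nm[2]
  conc <- as.numeric(standards[[conc_col]])
  intensity <- as.numeric(standards[[int_col]])
  ok <- is.finite(conc) & is.finite(intensity)
  conc <- conc[ok]; intensity <- intensity[ok]
  if (length(unique(conc)) < 3) {
    stop("calibration needs >= 3 distinct concentrations", call. = FALSE)
  }
  if (is.null(force_blank)) {
    fit <- stats::lm(intensity ~ conc, weights = weights)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  } else {
    y <- intensity - force_blank
    fit <- stats::lm(y ~ conc + 0, weights = weights)
    slope <- unname(stats::coef(fit)[1])
    intercept <- force_blank
  }
  pred <- slope * conc + intercept
  ss_res <- sum((intensity - pred)^2)
  ss_tot <- sum((intensity - mean(intensity))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  usable <- is.finite(slope) && slope > 0
  if (!usable) {
    warning("calibration slope is not positive; curve flagged unusable",
            call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 n_points = length(conc), conc_range = range(conc),
                 intensity_range = range(intensity), blank = intercept,
                 usable = usable),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration: I = %.4g * C + %.4g (R2 = %.4f, n = %d, C in [%.3g, %.3g] M)%s\n",
    x$slope, x$intercept, x$r2, x$n_points, x$conc_range[1], x$conc_range[2],
    if (x$usable) "" else "  [UNUSABLE]"))
  invisible(x)
}

#' Inverse-predict a concentration from a fluorescence intensity
#'
#' `(intensity - intercept) / slope`, floored at zero.  Flags are attached
#' for a negative raw estimate (`"negative_concentration"`) and for
#' extrapolation beyond the calibrated concentration range
#' (`"extrapolation"`).
#'
#' @param curve A usable [fit_calibration()] result.
#' @param intensity Measured intensity (arbitrary units).
#' @return List with `conc` (mol/L) and `flags` (character vector).
#' @export
concentration_from_intensity <- function(curve, intensity) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!isTRUE(curve$usable)) {
    stop("calibration curve is flagged unusable (non-positive slope)",
         call. = FALSE)
  }
  conc <- (intensity - curve$intercept) / curve$slope
  flags <- character()
  if (conc < 0) {
    flags <- c(flags, "negative_concentration")
    conc <- 0
  }
  if (conc > curve$conc_range[2] || conc < curve$conc_range[1]) {
    flags <- c(flags, "extrapolation")
  }
  list(conc = conc, flags = flags)
}

#' Absolute molecule count from concentration and volume
#'
#' `count = conc * volume * N_A`: the number of enzyme molecules in the
#' stripping solution.
#'
#' @param conc Concentration, mol/L (>= 0).
#' @param volume Solution volume, L (> 0); the stripping droplet is 200 uL
#'   by default.
#' @param N_A Avogadro constant.
#' @return Number of molecules.
#' @export
enzyme_count <- function(conc, volume = 200e-6, N_A = 6.02214076e23) {
  if (any(conc < 0)) stop("conc must be >= 0", call. = FALSE)
  if (any(volume <= 0)) stop("volume must be > 0", call. = FALSE)
  conc * volume * N_A
}

#' Enzymes per nanoparticle and per-enzyme footprint
#'
#' Relates the absolute enzyme count to the nanoparticle estimate of the same
#' electrode: `per_np = count / n_np` and
#' `footprint = s_total(nm2) / count`, which is algebraically identical to
#' `hemisphere_area(d) / per_np`.  Both routes are computed; a relative
#' disagreement above 0.1% (possible only through inconsistent inputs) is
#' flagged.
#'
#' @param count Number of enzymes released from the electrode.
#' @param np An [estimate_np()] result with `n_np > 0`.
#' @param conc Optional concentration (mol/L) to echo into the report.
#' @param volume Stripping solution volume, L.
#' @param flags Character vector of upstream flags to carry along.
#' @return An `enzyme_report`: `conc`, `count`, `per_np`, `footprint` (nm2,
#'   `NA` when `count` is 0), `volume`, `flags`.
#' @export
per_np_and_footprint <- function(count, np, conc = NA_real_,
                                 volume = 200e-6, flags = character()) {
  stopifnot(inherits(np, "np_estimate"))
  if (!is.finite(np$n_np) || np$n_np <= 0) {
    stop("nanoparticle count must be > 0", call. = FALSE)
  }
  if (count < 0) stop("enzyme count must be >= 0", call. = FALSE)
  per_np <- count / np$n_np
  if (count == 0) {
    footprint <- NA_real_
    flags <- c(flags, "zero_enzyme_count")
  } else {
    footprint <- cm2_to_nm2(np$s_total) / count
    alt <- hemisphere_area(np$d) / per_np
    if (abs(alt - footprint) > 1e-3 * footprint) {
      flags <- c(flags, "footprint_routes_disagree")
    }
  }
  structure(list(conc = conc, count = count, per_np = per_np,
                 footprint = footprint, volume = volume, flags = flags),
            class = "enzyme_report")
}

#' @export
print.enzyme_report <- function(x, ...) {
  cat("Enzyme report:\n")
  cat(sprintf("  count      : %.3g enzymes (%.3g mol/L in %.0f uL)\n",
              x$count, x$conc, x$volume * 1e6))
  cat(sprintf("  per NP     : %.3g enzymes/NP\n", x$per_np))
  cat(sprintf("  footprint  : %s nm2/enzyme\n",
              if (is.finite(x$footprint)) sprintf("%.3g", x$footprint) else "undefined"))
  if (length(x$flags)) cat("  flags      :", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Degree of labeling and protein concentration from UV-Vis absorbances
#'
#' Standard dye-conjugate arithmetic: the protein concentration is the
#' 280-nm absorbance corrected for the dye's own 280-nm contribution,
#' `protein_conc = (A280 - cf280 * A_dye) / eps_protein`, and the degree of
#' labeling is `DOL = A_dye / (eps_dye * protein_conc)`.  Typical values for
#' Alexa Fluor 488 conjugates are `eps_dye ~ 71000 L/(mol cm)` and
#' `cf280 ~ 0.11`; glucose oxidase `eps_protein ~ 267200 L/(mol cm)`.  These
#' are configuration inputs, not built-in claims.
#'
#' @param a_dye Absorbance at the dye maximum (e.g. 494 nm), 1-cm path.
#' @param a_280 Absorbance at 280 nm.
#' @param eps_dye Dye extinction coefficient, L/(mol cm).
#' @param eps_protein Protein extinction coefficient at 280 nm, L/(mol cm).
#' @param cf_280 Dye correction factor at 280 nm (dimensionless).
#' @return List with `dol` (fluorophores per protein) and `protein_conc`
#'   (mol/L).
#' @export
degree_of_labeling <- function(a_dye, a_280, eps_dye, eps_protein,
                               cf_280 = 0) {
  if (a_dye < 0 || a_280 < 0) stop("absorbances must be >= 0", call. = FALSE)
  if (eps_dye <= 0 || eps_protein <= 0) {
    stop("extinction coefficients must be > 0", call. = FALSE)
  }
  a_corr <- a_280 - cf_280 * a_dye
  if (a_corr <= 0) {
    stop("corrected A280 <= 0: dye correction exceeds the measured absorbance",
         call. = FALSE)
  }
  protein_conc <- a_corr / eps_protein
  dol <- if (a_dye == 0) 0 else a_dye / (eps_dye * protein_conc)
  list(dol = dol, protein_conc = protein_conc)
}
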