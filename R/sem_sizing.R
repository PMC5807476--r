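#' Build a particle table from SEM measurement exports
#'
#' Consumes the results-table layout of common image-analysis software:
#' either per-particle diameters (nm) or per-particle projected areas (nm2),
#' the latter converted to equivalent-circle diameters `d = 2 sqrt(A/pi)`.
#' Image segmentation itself is out of scope.
#'
#' @param diameters Numeric vector of particle diameters, nm (> 0), or `NULL`.
#' @param areas Numeric vector of particle projected areas, nm2 (> 0), used
#'   when `diameters` is `NULL`.
#' @param field_area Total imaged area, nm2 (required for coverage).
#' @param n_images Number of images contributing.
#' @param pixel_size nm per pixel (provenance only).
#' @return An object of class `particle_table`.
#' @export
particle_table <- function(diameters = NULL, areas = NULL, field_area = NULL,
                           n_images = 1, pixel_size = NA_real_) {
  if (is.null(diameters)) {
    if (is.null(areas)) stop("need diameters or areas", call. = FALSE)
    if (any(areas <= 0)) stop("areas must be > 0", call. = FALSE)
    diameters <- 2 * sqrt(areas / pi)
  }
  diameters <- as.numeric(diameters)
  if (any(diameters <= 0)) stop("diameters must be > 0", call. = FALSE)
  if (!is.null(field_area) && field_area <= 0) {
    stop("field_area must be > 0", call. = FALSE)
  }
  structure(list(diameters = diameters, field_area = field_area,
                 n_images = n_images, pixel_size = pixel_size),
            class = "particle_table")
}

#' Read a particle table from a delimited file
#'
#' Expects columns `(label, diameter_nm)` or `(label, area_nm2)` (header
#' required; extra columns ignored).
#'
#' @param path File path.
#' @param field_area Imaged area, nm2 (sidecar value, not in the table).
#' @param ... Passed to [particle_table()].
#' @return A [particle_table()].
#' @export
read_particle_table <- function(path, field_area = NULL, ...) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- tolower(names(df))
  if ("diameter_nm" %in% nm) {
    particle_table(diameters = df[[which(nm == "diameter_nm")[1]]],
                   field_area = field_area, ...)
  } else if ("area_nm2" %in% nm) {
    particle_table(areas = df[[which(nm == "area_nm2")[1]]],
                   field_area = field_area, ...)
  } else {
    stop("no diameter_nm or area_nm2 column in ", path, call. = FALSE)
  }
}

#' Fit a Gaussian to the binned diameter distribution
#'
#' Histograms the diameters with the given bin width and least-squares fits
#' `count = a * exp(-(d - mu)^2 / (2 sigma^2))` to the bin centers/counts,
#' mirroring how SEM size histograms are conventionally summarized.  The
#' adjusted R-squared uses 3 fitted parameters:
#' `adj_R2 = 1 - (1 - R2) (n_bins - 1) / (n_bins - 4)`.  Sample mean and SD
#' of the raw diameters are always reported alongside.
#'
#' With fewer than 30 particles, or a degenerate (zero-spread) sample, the
#' fit is skipped with a notice and only sample statistics are returned.
#'
#' @param t A [particle_table()].
#' @param bin_width Histogram bin width, nm (default 2).
#' @return List with `mu`, `sigma`, `adj_r2` (NA when the fit is skipped),
#'   `sample_mean`, `sample_sd`, `n`, `bin_width`, `fit_performed`.
#' @export
fit_diameter_distribution <- function(t, bin_width = 2) {
  stopifnot(inherits(t, "particle_table"))
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  d <- t$diameters
  out <- list(mu = NA_real_, sigma = NA_real_, adj_r2 = NA_real_,
              sample_mean = mean(d), sample_sd = stats::sd(d), n = length(d),
              bin_width = bin_width, fit_performed = FALSE)
  if (length(d) < 30) {
    message("fewer than 30 particles: Gaussian fit skipped, ",
            "sample statistics only")
    return(out)
  }
  if (out$sample_sd == 0) {
    message("zero spread in diameters: degenerate Gaussian fit refused")
    return(out)
  }
  breaks <- seq(floor(min(d) / bin_width) * bin_width,
                ceiling(max(d) / bin_width) * bin_width, by = bin_width)
  if (length(breaks) < 2) breaks <- c(breaks, breaks + bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  xb <- h$mids
  yb <- h$counts
  if (sum(yb > 0) < 5) {
    message("too few occupied bins for a Gaussian fit; sample statistics only")
    return(out)
  }
  start <- list(a = max(yb), mu = out$sample_mean, sigma = out$sample_sd)
  fit <- tryCatch(
    stats::nls(yb ~ a * exp(-(xb - mu)^2 / (2 * sigma^2)), start = start,
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    message("Gaussian fit did not converge; sample statistics only")
    return(out)
  }
  cf <- stats::coef(fit)
  pred <- cf[["a"]] * exp(-(xb - cf[["mu"]])^2 / (2 * cf[["sigma"]]^2))
  ss_res <- sum((yb - pred)^2)
  ss_tot <- sum((yb - mean(yb))^2)
  r2 <- 1 - ss_res / ss_tot
  n_bins <- length(xb)
  out$mu <- cf[["mu"]]
  out$sigma <- abs(cf[["sigma"]])
  out$adj_r2 <- 1 - (1 - r2) * (n_bins - 1) / (n_bins - 4)
  out$fit_performed <- TRUE
  out
}

#' Projected surface coverage from an SEM particle table
#'
#' `100 * sum(pi (d_i/2)^2) / field_area`: the summed projected particle
#' areas as a percentage of the imaged field.
#'
#' @param t A [particle_table()] with `field_area` set.
#' @return Coverage, percent.
#' @export
coverage_from_table <- function(t) {
  stopifnot(inherits(t, "particle_table"))
  if (is.null(t$field_area)) {
    stop("field_area is required for coverage", call. = FALSE)
  }
  if (length(t$diameters) == 0) return(0)
  100 * sum(pi * (t$diameters / 2)^2) / t$field_area
}
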