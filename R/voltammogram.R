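#' Construct and validate a voltammogram
#'
#' A voltammogram is an ordered potential/current sweep with a scan rate,
#' cycle segmentation and reference-electrode metadata.  The sign convention
#' throughout the package is anodic (oxidation) current positive, cathodic
#' negative.
#'
#' @param potential Numeric vector of applied potentials, V, vs `reference`.
#' @param current Numeric vector of currents, A (anodic positive).
#' @param scan_rate Scan rate, V/s (> 0).
#' @param reference Either a reference name (`"NHE"`, `"AgAgCl_sat"`,
#'   `"CuCuSO4"`, `"AgWire_calibrated"`) or a list `list(name=, offset_V=)`
#'   where `offset_V` is the potential of that reference vs NHE.  Named
#'   defaults are provided for Ag/AgCl(sat) (+0.197 V) and Cu/CuSO4
#'   (+0.316 V); a calibrated Ag wire has no default and requires an explicit
#'   offset.
#' @param meta Named list of free-form provenance (electrolyte, electrode
#'   diameter in mm, ...).
#' @param cycles Optional list of `c(start, end)` index pairs, one per sweep
#'   cycle.  When `NULL` they are detected from potential-direction
#'   reversals (see [detect_cycles()]).
#' @return An object of class `voltammogram`.
#' @export
voltammogram <- function(potential, current, scan_rate,
                         reference = "NHE", meta = list(), cycles = NULL) {
  potential <- as.numeric(potential)
  current <- as.numeric(current)
  if (length(potential) != length(current)) {
    stop("potential and current must have equal length", call. = FALSE)
  }
  if (length(potential) < 2) {
    stop("a voltammogram needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(potential) || anyNA(current) ||
      any(!is.finite(potential)) || any(!is.finite(current))) {
    stop("potential and current must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (!is.numeric(scan_rate) || length(scan_rate) != 1 || scan_rate <= 0) {
    stop("scan_rate must be a single positive number (V/s)", call. = FALSE)
  }
  ref <- resolve_reference(reference)
  seg <- detect_segments(potential)
  if (is.null(cycles)) cycles <- pair_segments(seg)
  structure(list(potential = potential, current = current,
                 scan_rate = scan_rate, cycles = cycles, segments = seg,
                 reference = ref, meta = meta),
            class = "voltammogram")
}

# Reference-electrode offsets vs NHE, volts.  Ag/AgCl(sat KCl) and Cu/CuSO4
# values are the standard handbook numbers; a calibrated Ag wire must carry a
# measured offset.
.reference_offsets <- c(NHE = 0, AgAgCl_sat = 0.197, CuCuSO4 = 0.316)

resolve_reference <- function(reference) {
  if (is.list(reference)) {
    name <- reference$name %||% "custom"
    off <- reference$offset_V
    if (is.null(off) && name %in% names(.reference_offsets)) {
      off <- .reference_offsets[[name]]
    }
    if (is.null(off) || !is.finite(off)) {
      stop("reference '", name, "' needs a finite numeric offset_V vs NHE",
           call. = FALSE)
    }
    return(list(name = name, offset_V = as.numeric(off)))
  }
  name <- as.character(reference)
  if (name == "AgWire_calibrated") {
    stop("AgWire_calibrated has no default offset; supply ",
         "list(name = 'AgWire_calibrated', offset_V = <measured value>)",
         call. = FALSE)
  }
  if (!name %in% names(.reference_offsets)) {
    stop("unknown reference electrode: ", name, call. = FALSE)
  }
  list(name = name, offset_V = .reference_offsets[[name]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect monotone sweep segments of a potential program
#'
#' Splits the potential vector at direction reversals.  A 3-sample hysteresis
#' suppresses spurious reversals from ADC jitter: a direction change only
#' opens a new segment if the new direction persists for at least 3 samples
#' (or reaches the end of the trace).
#'
#' @param potential Numeric potential vector.
#' @param hysteresis Minimum run length for a direction change to count.
#' @return A data.frame with columns `start`, `end`, `direction`
#'   (+1 increasing, -1 decreasing).
#' @export
detect_segments <- function(potential, hysteresis = 3) {
  n <- length(potential)
  dE <- diff(potential)
  s <- sign(dE)
  # carry direction through flat steps
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- if (i > 1) s[i - 1] else 0
  if (all(s == 0)) {
    return(data.frame(start = 1L, end = n, direction = 0L))
  }
  s[s == 0] <- s[which(s != 0)[1]]
  # run-length encode, then absorb runs shorter than the hysteresis
  r <- rle(s)
  while (length(r$lengths) > 1 && any(r$lengths < hysteresis)) {
    i <- which(r$lengths < hysteresis)[1]
    j <- if (i == 1) 2L else i - 1L
    r$lengths[j] <- r$lengths[j] + r$lengths[i]
    r$lengths <- r$lengths[-i]
    r$values <- r$values[-i]
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths) + 1L       # sample index closing each run
  starts <- c(1L, ends[-length(ends)]) # vertex sample shared between segments
  data.frame(start = starts, end = ends, direction = as.integer(r$values))
}

pair_segments <- function(seg) {
  cycles <- list()
  i <- 1L
  while (i <= nrow(seg)) {
    if (i + 1L <= nrow(seg) && seg$direction[i + 1L] == -seg$direction[i]) {
      cycles[[length(cycles) + 1L]] <- c(seg$start[i], seg$end[i + 1L])
      i <- i + 2L
    } else {
      cycles[[length(cycles) + 1L]] <- c(seg$start[i], seg$end[i])
      i <- i + 1L
    }
  }
  cycles
}

#' Detect sweep cycles of a voltammogram
#'
#' A cycle is either a single monotone ramp (linear sweep) or one triangular
#' excursion (up-down or down-up pair of segments).
#'
#' @inheritParams detect_segments
#' @return List of `c(start, end)` index pairs.
#' @export
detect_cycles <- function(potential, hysteresis = 3) {
  pair_segments(detect_segments(potential, hysteresis))
}

#' Shift a voltammogram to the NHE potential scale
#'
#' Adds the stored reference offset to all potentials and re-labels the
#' reference as NHE.  Idempotent: applying it twice equals applying it once.
#'
#' @param v A [voltammogram()].
#' @return A voltammogram on the NHE scale (offset 0).
#' @export
to_nhe <- function(v) {
  stopifnot(inherits(v, "voltammogram"))
  off <- v$reference$offset_V
  if (!is.finite(off)) stop("reference offset unknown", call. = FALSE)
  v$potential <- v$potential + off
  v$reference <- list(name = "NHE", offset_V = 0)
  v
}

#' @export
print.voltammogram <- function(x, ...) {
  cat(sprintf(
    "Voltammogram: %d samples, %d cycle(s), %.3g V/s, E in [%.3g, %.3g] V vs %s\n",
    length(x$potential), length(x$cycles), x$scan_rate,
    min(x$potential), max(x$potential), x$reference$name))
  invisible(x)
}
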