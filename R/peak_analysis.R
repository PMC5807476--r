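#' Define a peak integration window
#'
#' @param e_start,e_end Window bounds, V vs NHE (`e_start < e_end`).
#' @param direction `"anodic"` (integrate on positive-going sweeps) or
#'   `"cathodic"` (negative-going).  Only samples recorded while the
#'   potential moves in the stated direction contribute, so the return sweep
#'   of a CV cannot cancel or double-count the peak.
#' @param cycles Integer vector of cycle indices, or `"all"`.
#' @return An object of class `peak_window`.
#' @export
peak_window <- function(e_start, e_end, direction = c("anodic", "cathodic"),
                        cycles = "all") {
  direction <- match.arg(direction)
  if (!is.numeric(e_start) || !is.numeric(e_end) || e_end <= e_start) {
    stop("need e_start < e_end", call. = FALSE)
  }
  structure(list(e_start = e_start, e_end = e_end, direction = direction,
                 cycles = cycles),
            class = "peak_window")
}

#' Default window for the gold-oxide reduction peak
#'
#' Cathodic window bracketing the ~+1.1 V (vs NHE) oxide-reduction peak seen
#' on the downward sweep in sulfuric acid.
#' @param cycles Cycle selection, default all.
#' @return A [peak_window()].
#' @export
oxide_window <- function(cycles = "all") {
  peak_window(0.9, 1.35, "cathodic", cycles)
}

#' Default window for the anodic gold-stripping peak
#'
#' Anodic window bracketing the ~+1.3 V (vs NHE) gold dissolution peak of the
#' stripping cycles.
#' @param cycles Cycle selection, default all (residual charge in later
#'   cycles is then included in the total).
#' @return A [peak_window()].
#' @export
stripping_window <- function(cycles = "all") {
  peak_window(1.1, 1.5, "anodic", cycles)
}

select_cycles <- function(v, w) {
  n <- length(v$cycles)
  if (identical(w$cycles, "all")) return(seq_len(n))
  idx <- as.integer(w$cycles)
  if (any(idx < 1 | idx > n)) {
    stop("cycle selection out of range (trace has ", n, " cycles)",
         call. = FALSE)
  }
  idx
}

# Samples of cycle `ci` inside window `w`, restricted to the matching sweep
# direction.  Returns indices into the trace in sweep order.
window_samples <- function(v, w, ci) {
  cyc <- v$cycles[[ci]]
  dir_wanted <- if (w$direction == "anodic") 1L else -1L
  seg <- v$segments
  seg <- seg[seg$start < cyc[2] & seg$end > cyc[1] & seg$direction == dir_wanted, ,
             drop = FALSE]
  idx <- integer(0)
  for (k in seq_len(nrow(seg))) {
    i0 <- max(seg$start[k], cyc[1]); i1 <- min(seg$end[k], cyc[2])
    idx <- c(idx, seq(i0, i1))
  }
  idx[v$potential[idx] >= w$e_start & v$potential[idx] <= w$e_end]
}

#' Subtract a baseline from a voltammetric peak window
#'
#' For `linear_anchors`, the baseline of each cycle is the straight line
#' through two anchor points, each the median of the 5 samples at the low- and
#' high-potential edges of the window (on the direction-matching sweep).  For
#' `flat`, the baseline is the zero line.  The anchor record is retained for
#' provenance.
#'
#' @param v A [voltammogram()] (potentials vs NHE).
#' @param w A [peak_window()].
#' @param method `"linear_anchors"` or `"flat"`.
#' @param n_anchor Samples per edge anchor (default 5).
#' @return A `corrected_trace`: list with one entry per selected cycle, each
#'   holding `cycle`, `index`, `potential`, `current`, `baseline`,
#'   `corrected`, and `anchors`.
#' @export
subtract_baseline <- function(v, w, method = c("linear_anchors", "flat"),
                              n_anchor = 5) {
  method <- match.arg(method)
  stopifnot(inherits(v, "voltammogram"), inherits(w, "peak_window"))
  rng <- range(v$potential)
  if (w$e_start > rng[2] || w$e_end < rng[1]) {
    stop(sprintf("window [%.3g, %.3g] V lies outside the sweep range [%.3g, %.3g] V",
                 w$e_start, w$e_end, rng[1], rng[2]), call. = FALSE)
  }
  out <- list()
  for (ci in select_cycles(v, w)) {
    idx <- window_samples(v, w, ci)
    if (length(idx) == 0) next  # cycle has no matching-direction samples
    if (length(idx) < n_anchor) {
      stop("fewer than ", n_anchor, " samples inside the window in cycle ", ci,
           " (insufficient potential resolution)", call. = FALSE)
    }
    E <- v$potential[idx]
    i_raw <- v$current[idx]
    ord <- order(E)
    if (method == "flat") {
      base <- rep(0, length(idx))
      anchors <- NULL
    } else {
      lo <- ord[seq_len(min(n_anchor, length(ord)))]
      hi <- rev(ord)[seq_len(min(n_anchor, length(ord)))]
      a_lo <- c(E = mean(E[lo]), i = stats::median(i_raw[lo]))
      a_hi <- c(E = mean(E[hi]), i = stats::median(i_raw[hi]))
      slope <- if (a_hi["E"] > a_lo["E"]) {
        (a_hi["i"] - a_lo["i"]) / (a_hi["E"] - a_lo["E"])
      } else 0
      base <- a_lo[["i"]] + slope * (E - a_lo[["E"]])
      anchors <- list(low = a_lo, high = a_hi)
    }
    out[[length(out) + 1L]] <- list(
      cycle = ci, index = idx, potential = E, current = i_raw,
      baseline = base, corrected = i_raw - base, anchors = anchors)
  }
  if (length(out) == 0) {
    stop("no samples in the stated sweep direction fall inside the window",
         call. = FALSE)
  }
  structure(list(cycles = out, window = w, method = method,
                 scan_rate = v$scan_rate),
            class = "corrected_trace")
}

#' Integrate a baseline-corrected voltammetric peak to a charge
#'
#' Per cycle, the faradaic charge is the trapezoidal integral of the
#' magnitude of the baseline-corrected current over potential, divided by the
#' scan rate: `q_cycle = (1/nu) * integral |i_corr(E)| dE`, restricted to
#' samples swept in the window's stated direction.  The total is the sum over
#' the selected cycles; the peak potential is the extremum of the corrected
#' current.
#'
#' @inheritParams subtract_baseline
#' @return A `charge_result`: list with `q` (C, >= 0), `e_peak` (V),
#'   `per_cycle` (named numeric vector), `baseline` (method + anchors),
#'   `window`, `scan_rate`.
#' @export
integrate_charge <- function(v, w, method = c("linear_anchors", "flat"),
                             n_anchor = 5) {
  method <- match.arg(method)
  if (!is.numeric(v$scan_rate) || v$scan_rate <= 0) {
    stop("scan_rate must be positive", call. = FALSE)
  }
  ct <- subtract_baseline(v, w, method, n_anchor)
  per_cycle <- numeric(0)
  anchors <- list()
  best <- c(val = -Inf, e = NA_real_)
  for (cc in ct$cycles) {
    E <- cc$potential
    ic <- abs(cc$corrected)
    ord <- order(E)
    q_c <- sum(diff(E[ord]) * (ic[ord][-1] + ic[ord][-length(ic)]) / 2) /
      v$scan_rate
    per_cycle[as.character(cc$cycle)] <- q_c
    anchors[[as.character(cc$cycle)]] <- cc$anchors
    k <- which.max(ic)
    if (ic[k] > best["val"]) best <- c(val = ic[k], e = E[k])
  }
  structure(list(
    q = sum(per_cycle), e_peak = unname(best["e"]), per_cycle = per_cycle,
    baseline = list(method = method, n_anchor = n_anchor, anchors = anchors),
    window = w, scan_rate = v$scan_rate
  ), class = "charge_result")
}

#' @export
print.charge_result <- function(x, ...) {
  cat(sprintf("Charge: %.4g C over %d cycle(s); peak at %.3g V; baseline: %s\n",
              x$q, length(x$per_cycle), x$e_peak, x$baseline$method))
  invisible(x)
}
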