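# Topographic prominence of each candidate extremum of x (maxima if
# kind = "max"). For a peak, walk out to the nearest higher sample on each
# side; the prominence is peak height minus the higher of the two interval
# minima (trace ends count as bases).
peak_prominence <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    left <- p; lmin <- x[p]
    while (left > 1 && x[left] <= x[p]) { left <- left - 1L; lmin <- min(lmin, x[left]) }
    lbase <- if (x[left] > x[p]) lmin else min(x[seq_len(p)])
    right <- p; rmin <- x[p]
    while (right < n && x[right] <= x[p]) { right <- right + 1L; rmin <- min(rmin, x[right]) }
    rbase <- if (x[right] > x[p]) rmin else min(x[seq.int(p, n)])
    x[p] - max(lbase, rbase)
  }, numeric(1))
}

# Greedy separation filter: keep candidates in decreasing prominence order,
# dropping any within min_sep samples of an already kept one.
enforce_separation <- function(idx, prom, min_sep) {
  keep <- integer(0)
  for (j in order(prom, decreasing = TRUE)) {
    if (all(abs(idx[j] - idx[keep]) >= min_sep)) keep <- c(keep, j)
  }
  sort(idx[keep])
}

#' Detect breathing extrema in a trace
#'
#' Finds end-inhalation (local maxima) and end-exhalation (local minima)
#' samples with at least `min_prominence` topographic prominence and
#' pairwise separation of `min_separation` seconds, then enforces strict
#' max/min alternation by discarding the lower-prominence member of
#' same-type adjacent pairs.
#'
#' @param trace An `rm_surrogate_trace`, or a numeric position vector.
#' @param dt Sampling interval in seconds (taken from the trace if given).
#' @param min_prominence Minimum prominence in mm; defaults to 20% of the
#'   trace interquartile range.
#' @param min_separation Minimum separation between same-type extrema, in
#'   seconds (default 1 s; rejects cardiac/noise ripple at 5 Hz sampling).
#' @param smooth_width Optional moving-average width in samples (odd,
#'   0 = no smoothing) applied before detection; reported indices refer to
#'   the original trace.
#' @return An object of class `rm_breath_cycles` with sorted index vectors
#'   `end_inhalation` and `end_exhalation`, the positions and `dt`.
#' @export
detect_extrema <- function(trace, dt = 0.2, min_prominence = NULL,
                           min_separation = 1, smooth_width = 0) {
  if (inherits(trace, "rm_surrogate_trace")) {
    dt <- trace$dt
    x <- trace$positions
  } else {
    x <- as.numeric(trace)
  }
  if (length(x) < 3) err_invalid("trace too short for extrema detection (need >= 3 samples)")
  xs <- x
  if (smooth_width >= 2) {
    k <- as.integer(smooth_width)
    if (k %% 2L == 0L) k <- k + 1L
    xs <- stats::filter(x, rep(1 / k, k), sides = 2)
    xs[is.na(xs)] <- x[is.na(xs)]
    xs <- as.numeric(xs)
  }
  if (is.null(min_prominence)) min_prominence <- 0.2 * IQR(xs)
  s <- sign(diff(xs))
  ds <- diff(s)
  maxima <- which(ds < 0) + 1L
  minima <- which(ds > 0) + 1L
  min_sep <- max(1L, round(min_separation / dt))
  filt <- function(idx, y) {
    if (length(idx) == 0L) return(integer(0))
    prom <- peak_prominence(y, idx)
    idx <- idx[prom >= min_prominence]
    prom <- prom[prom >= min_prominence]
    enforce_separation(idx, prom, min_sep)
  }
  maxima <- filt(maxima, xs)
  minima <- filt(minima, -xs)
  # Alternation: among same-type neighbours keep the more prominent one.
  all_idx <- c(maxima, minima)
  type <- rep(c(1L, -1L), c(length(maxima), length(minima)))
  o <- order(all_idx)
  all_idx <- all_idx[o]; type <- type[o]
  prom_all <- numeric(length(all_idx))
  prom_all[type == 1L] <- if (length(maxima)) peak_prominence(xs, all_idx[type == 1L]) else numeric(0)
  prom_all[type == -1L] <- if (length(minima)) peak_prominence(-xs, all_idx[type == -1L]) else numeric(0)
  repeat {
    same <- which(diff(type) == 0L)
    if (length(same) == 0L) break
    j <- same[1]
    drop <- if (prom_all[j] >= prom_all[j + 1]) j + 1L else j
    all_idx <- all_idx[-drop]; type <- type[-drop]; prom_all <- prom_all[-drop]
  }
  structure(
    list(end_inhalation = all_idx[type == 1L], end_exhalation = all_idx[type == -1L],
         positions = x, dt = dt),
    class = "rm_breath_cycles"
  )
}

#' @export
print.rm_breath_cycles <- function(x, ...) {
  cat(sprintf("<rm_breath_cycles>  %d end-inhalations, %d end-exhalations over %.1f s\n",
              length(x$end_inhalation), length(x$end_exhalation),
              (length(x$positions) - 1) * x$dt))
  invisible(x)
}

#' Mean respiratory period
#'
#' The average interval between two consecutive end-inhalations.
#'
#' @param cycles An `rm_breath_cycles` from [detect_extrema()].
#' @return Period in seconds.
#' @export
respiratory_period <- function(cycles) {
  stopifnot(inherits(cycles, "rm_breath_cycles"))
  if (length(cycles$end_inhalation) < 2) {
    err_insufficient_cycles("need at least two end-inhalations for a period estimate")
  }
  mean(diff(cycles$end_inhalation)) * cycles$dt
}

#' Mean respiratory amplitude
#'
#' The average absolute difference between the end-exhalation and
#' end-inhalation positions of single respiratory cycles; each
#' end-inhalation is paired with the immediately preceding end-exhalation.
#'
#' @inheritParams respiratory_period
#' @return Amplitude in mm (peak-to-trough).
#' @export
respiratory_amplitude <- function(cycles) {
  stopifnot(inherits(cycles, "rm_breath_cycles"))
  amps <- numeric(0)
  for (p in cycles$end_inhalation) {
    prev <- cycles$end_exhalation[cycles$end_exhalation < p]
    if (length(prev) > 0) {
      amps <- c(amps, abs(cycles$positions[p] - cycles$positions[max(prev)]))
    }
  }
  if (length(amps) == 0) {
    err_insufficient_cycles("no complete exhale-to-inhale cycle found")
  }
  mean(amps)
}

#' Combine per-direction amplitudes into a 3D motion amplitude
#'
#' Euclidean norm of the LR/SI/AP amplitudes. How per-direction amplitudes
#' combine into a single 3D figure is a convention, not a law; the
#' Euclidean norm is this package's documented default.
#'
#' @param amplitudes Numeric vector of three non-negative amplitudes (mm),
#'   ordered LR, SI, AP.
#' @return 3D amplitude in mm.
#' @export
amplitude_3d <- function(amplitudes) {
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) != 3 || !all(is.finite(amplitudes)) || any(amplitudes < 0)) {
    err_invalid("amplitudes must be three finite non-negative values")
  }
  sqrt(sum(amplitudes^2))
}

#' Correlation between surrogate and target motion
#'
#' Pearson correlation between the AP surrogate trace and the target trace
#' in one direction.
#'
#' @param surrogate Numeric vector (or `rm_surrogate_trace`) of surrogate
#'   AP positions.
#' @param target Numeric vector, or an `rm_target_trace` / target matrix
#'   from which `direction` is taken.
#' @param direction One of `"LR"`, `"SI"`, `"AP"` (used when `target` has
#'   3 columns).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
surrogate_target_correlation <- function(surrogate, target, direction = "SI") {
  if (inherits(surrogate, "rm_surrogate_trace")) surrogate <- surrogate$positions
  if (inherits(target, "rm_target_trace")) target <- target$positions
  if (is.matrix(target)) {
    direction <- match.arg(direction, DIRECTIONS)
    target <- target[, direction]
  }
  if (length(surrogate) != length(target) || length(surrogate) < 3) {
    err_invalid("surrogate and target must have equal length >= 3")
  }
  if (sd(surrogate) == 0 || sd(target) == 0) {
    err_undefined_correlation("correlation undefined for a zero-variance trace")
  }
  cor(surrogate, target)
}

#' Respiratory descriptors of a scan
#'
#' Summarises a scan: mean respiratory period, per-marker surrogate
#' amplitude, per-direction target amplitude (measured at the breathing
#' extrema of the marker-averaged surrogate, which is robust for
#' low-amplitude target directions), 3D target amplitude and
#' surrogate-target correlations.
#'
#' @param scan An `rm_scan`.
#' @param ... Passed to [detect_extrema()].
#' @return A one-row `data.frame` with unit-suffixed columns.
#' @export
scan_descriptors <- function(scan, ...) {
  stopifnot(inherits(scan, "rm_scan"))
  wm <- rowMeans(surrogate_matrix(scan))
  cyc <- detect_extrema(wm, dt = scan$dt, ...)
  period <- respiratory_period(cyc)
  marker_amp <- vapply(1:3, function(i) {
    respiratory_amplitude(detect_extrema(scan$surrogates[[i]], ...))
  }, numeric(1))
  tm <- target_matrix(scan)
  target_amp <- vapply(DIRECTIONS, function(d) {
    amps <- numeric(0)
    for (p in cyc$end_inhalation) {
      prev <- cyc$end_exhalation[cyc$end_exhalation < p]
      if (length(prev) > 0) amps <- c(amps, abs(tm[p, d] - tm[max(prev), d]))
    }
    if (length(amps) == 0) NA_real_ else mean(amps)
  }, numeric(1))
  cors <- vapply(DIRECTIONS, function(d) surrogate_target_correlation(wm, tm, d), numeric(1))
  t3d <- if (all(is.finite(target_amp))) amplitude_3d(target_amp) else NA_real_
  out <- data.frame(
    scan_id = scan$scan_id, period_s = period,
    marker1_amplitude_mm = marker_amp[1], marker2_amplitude_mm = marker_amp[2],
    marker3_amplitude_mm = marker_amp[3],
    target_lr_amplitude_mm = target_amp["LR"], target_si_amplitude_mm = target_amp["SI"],
    target_ap_amplitude_mm = target_amp["AP"],
    target_3d_amplitude_mm = t3d,
    cor_lr = cors["LR"], cor_si = cors["SI"], cor_ap = cors["AP"],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
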