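#' Patient-axis direction labels
#'
#' The three patient axes along which target motion is resolved:
#' left-right (LR), superior-inferior (SI) and anterior-posterior (AP).
#' Every target-side quantity in the package is indexed by these names.
#'
#' @format Character vector of length 3: `c("LR", "SI", "AP")`.
#' @export
DIRECTIONS <- c("LR", "SI", "AP")

#' Construct a surrogate marker trace
#'
#' One infrared abdominal marker tracked along the AP axis, uniformly
#' sampled at interval `dt` (0.2 s nominal, i.e. 5 Hz).
#'
#' @param marker_id Integer marker number, one of 1, 2, 3.
#' @param positions Numeric vector of AP positions in mm; finite, length >= 2.
#' @param dt Sampling interval in seconds.
#' @return An object of class `rm_surrogate_trace`.
#' @export
new_surrogate_trace <- function(marker_id, positions, dt = 0.2) {
  if (!is_scalar_number(marker_id) || !(marker_id %in% 1:3)) {
    err_invalid("marker_id must be 1, 2 or 3")
  }
  positions <- as.numeric(positions)
  if (length(positions) < 2 || !all(is.finite(positions))) {
    err_invalid("surrogate positions must be finite and of length >= 2")
  }
  if (!is_scalar_number(dt) || dt <= 0) err_invalid("dt must be > 0")
  structure(
    list(marker_id = as.integer(marker_id), positions = positions, dt = dt),
    class = "rm_surrogate_trace"
  )
}

#' Construct a 3D target trace
#'
#' The triangulated 3D position of the fiducial marker nearest the tumour,
#' one row per sample, columns LR/SI/AP in mm.
#'
#' @param positions Numeric matrix with 3 columns (LR, SI, AP), in mm.
#' @param dt Sampling interval in seconds.
#' @return An object of class `rm_target_trace`.
#' @export
new_target_trace <- function(positions, dt = 0.2) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) err_invalid("target positions must have 3 columns (LR, SI, AP)")
  if (nrow(positions) < 2 || !all(is.finite(positions))) {
    err_invalid("target positions must be finite and of length >= 2")
  }
  storage.mode(positions) <- "double"
  colnames(positions) <- DIRECTIONS
  rownames(positions) <- NULL
  if (!is_scalar_number(dt) || dt <= 0) err_invalid("dt must be > 0")
  structure(list(positions = positions, dt = dt), class = "rm_target_trace")
}

#' Construct a scan
#'
#' A scan pairs three surrogate traces with the actual 3D target trace over
#' the same sampling grid; it is the atomic unit of model training and
#' validation. A 70-s acquisition at 0.2 s yields the nominal 351 samples.
#'
#' @param scan_id Character scan identifier.
#' @param surrogates List of three [new_surrogate_trace()] objects with
#'   marker ids exactly 1, 2, 3.
#' @param target A [new_target_trace()] object of the same length and `dt`.
#' @param acquired_at Acquisition time in seconds since an arbitrary epoch
#'   (metadata only, used for elapsed-time reporting between scans).
#' @return An object of class `rm_scan`.
#' @export
new_scan <- function(scan_id, surrogates, target, acquired_at = 0) {
  if (!is.character(scan_id) || length(scan_id) != 1L) err_invalid("scan_id must be a string")
  if (!is.list(surrogates) || length(surrogates) != 3L ||
      !all(vapply(surrogates, inherits, logical(1), "rm_surrogate_trace"))) {
    err_invalid("surrogates must be a list of exactly three surrogate traces")
  }
  ids <- sort(vapply(surrogates, function(s) s$marker_id, integer(1)))
  if (!identical(ids, 1:3)) err_invalid("surrogate marker ids must be exactly {1, 2, 3}")
  surrogates <- surrogates[order(vapply(surrogates, function(s) s$marker_id, integer(1)))]
  if (!inherits(target, "rm_target_trace")) err_invalid("target must be a target trace")
  n <- nrow(target$positions)
  dts <- c(vapply(surrogates, function(s) s$dt, numeric(1)), target$dt)
  if (max(dts) - min(dts) > 1e-9) err_invalid("all traces in a scan must share dt")
  lens <- vapply(surrogates, function(s) length(s$positions), integer(1))
  if (!all(lens == n)) err_invalid("all traces in a scan must have the same length")
  if (inherits(acquired_at, "POSIXct")) acquired_at <- as.numeric(acquired_at)
  if (!is_scalar_number(acquired_at)) err_invalid("acquired_at must be a single time value")
  structure(
    list(scan_id = scan_id, surrogates = surrogates, target = target,
         acquired_at = acquired_at, dt = target$dt, n_samples = n),
    class = "rm_scan"
  )
}

#' @export
print.rm_scan <- function(x, ...) {
  cat(sprintf("<rm_scan '%s'>  %d samples @ dt = %g s (%.1f s)\n",
              x$scan_id, x$n_samples, x$dt, (x$n_samples - 1) * x$dt))
  amp <- apply(surrogate_matrix(x), 2, function(w) diff(range(w)))
  cat(sprintf("  surrogate peak-to-peak (mm): %s\n",
              paste(sprintf("%.1f", amp), collapse = ", ")))
  tr <- apply(target_matrix(x), 2, function(p) diff(range(p)))
  cat(sprintf("  target range LR/SI/AP (mm): %s\n",
              paste(sprintf("%.1f", tr), collapse = ", ")))
  invisible(x)
}

#' Number of samples in a scan
#' @param scan An `rm_scan`.
#' @return Integer sample count.
#' @export
n_samples <- function(scan) {
  stopifnot(inherits(scan, "rm_scan"))
  scan$n_samples
}

#' Surrogate positions of a scan as a matrix
#' @param scan An `rm_scan`.
#' @return Numeric matrix, one column per marker (1..3), in mm.
#' @export
surrogate_matrix <- function(scan) {
  stopifnot(inherits(scan, "rm_scan"))
  m <- vapply(scan$surrogates, function(s) s$positions, numeric(scan$n_samples))
  colnames(m) <- paste0("marker", 1:3)
  m
}

#' Target positions of a scan as a matrix
#' @param scan An `rm_scan`.
#' @return Numeric matrix with columns LR, SI, AP, in mm.
#' @export
target_matrix <- function(scan) {
  stopifnot(inherits(scan, "rm_scan"))
  scan$target$positions
}

#' Split a scan into modeling and validating sessions
#'
#' The first half of the samples (floor(n/2)) forms the modeling session,
#' the remainder the validating session; for the nominal 351-sample scan the
#' split is 175/176. Indices are 1-based and contiguous.
#'
#' @param x An `rm_scan`, or a single integer sample count.
#' @return An object of class `rm_session_split` with elements `modeling`
#'   and `validating` (integer index vectors) and `n`.
#' @export
split_sessions <- function(x) {
  n <- if (inherits(x, "rm_scan")) x$n_samples else {
    if (!is_scalar_number(x) || x != round(x)) err_invalid("n must be an integer count")
    as.integer(x)
  }
  if (n < 4) err_invalid("scan too short to split (need at least 4 samples)")
  m <- n %/% 2L
  structure(
    list(modeling = seq_len(m), validating = seq.int(m + 1L, n), n = as.integer(n)),
    class = "rm_session_split"
  )
}

#' Sample count of a uniformly sampled acquisition
#'
#' Inclusive of the sample at t = 0: a 70-s acquisition at dt = 0.2 s has
#' 351 samples.
#'
#' @param duration_s Acquisition duration in seconds (positive multiple of `dt`).
#' @param dt Sampling interval in seconds.
#' @return Integer sample count `duration_s/dt + 1`.
#' @export
sample_count <- function(duration_s, dt) {
  period_steps(duration_s, dt) + 1L
}

#' Trailing window of the modeling session
#'
#' Returns the last `T/dt` indices of the modeling session — the training
#' window for model fitting (modeling period T_M) or the median window for
#' baseline-drift correction (correction period T_C). Windows always end at
#' the last modeling-session sample so that training never touches
#' validating data.
#'
#' @param split An `rm_session_split`.
#' @param T Window length in seconds (positive multiple of `dt`).
#' @param dt Sampling interval in seconds.
#' @param need_predecessor If `TRUE`, every returned index is guaranteed to
#'   have a predecessor sample inside the scan (required when velocities are
#'   computed on the window); if the literal window would start at the first
#'   scan sample, that sample is dropped.
#' @return Integer vector of scan indices.
#' @export
tail_window <- function(split, T, dt, need_predecessor = FALSE) {
  stopifnot(inherits(split, "rm_session_split"))
  m <- period_steps(T, dt)
  mod <- split$modeling
  if (m > length(mod)) {
    err_invalid(sprintf("window of %g s (%d samples) exceeds the %d-sample modeling session",
                        T, m, length(mod)))
  }
  w <- mod[seq.int(length(mod) - m + 1L, length(mod))]
  if (need_predecessor && w[1] == 1L) {
    w <- w[-1]
    if (length(w) == 0L) err_invalid("window has no sample with an available predecessor")
  }
  w
}
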