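#' Surrogate baseline drift between two scans
#'
#' The baseline of each scan is the median surrogate position over the last
#' `T_C` seconds of its modeling session (the window immediately prior to
#' the validating session); the drift is scan B's baseline minus scan A's.
#'
#' @param scan_a,scan_b `rm_scan` objects (model source and estimation
#'   target scan, respectively).
#' @param marker_id Marker number (1..3).
#' @param T_C Correction period in seconds.
#' @return Baseline drift in mm (scalar).
#' @export
surrogate_drift <- function(scan_a, scan_b, marker_id, T_C) {
  stopifnot(inherits(scan_a, "rm_scan"), inherits(scan_b, "rm_scan"))
  wa <- tail_window(split_sessions(scan_a), T_C, scan_a$dt)
  wb <- tail_window(split_sessions(scan_b), T_C, scan_b$dt)
  median(scan_b$surrogates[[marker_id]]$positions[wb]) -
    median(scan_a$surrogates[[marker_id]]$positions[wa])
}

#' Remove a baseline offset from a surrogate trace
#'
#' Every sample is shifted by `-bd_ir`; velocities are unaffected.
#'
#' @param trace An `rm_surrogate_trace`.
#' @param bd_ir Baseline drift to remove (mm).
#' @return The corrected `rm_surrogate_trace`.
#' @export
correct_surrogate <- function(trace, bd_ir) {
  stopifnot(inherits(trace, "rm_surrogate_trace"))
  if (!is_scalar_number(bd_ir)) err_invalid("bd_ir must be a finite scalar")
  trace$positions <- trace$positions - bd_ir
  trace
}

#' Target baseline drift between two scans
#'
#' Residual per-direction offset of the (surrogate-corrected) estimates on
#' scan B relative to an anchor baseline: with `anchor = "scan_a"` (the
#' verbatim definition) the anchor is the median of scan A's actual target
#' positions over scan A's correction window; with `anchor = "scan_b"` it
#' is the median of scan B's actual target positions over scan B's window
#' (the variant under which a genuine target baseline shift is removed).
#' For the phase-linear model the anchor is always the centroid of scan A's
#' eight phase-averaged target positions.
#'
#' @inheritParams surrogate_drift
#' @param model An `rm_quadratic_model` or `rm_phase_linear_model` fitted
#'   on scan A.
#' @param anchor `"scan_a"` or `"scan_b"`.
#' @param bd_ir Optional numeric vector of three per-marker surrogate
#'   drifts; computed via [surrogate_drift()] when omitted.
#' @param per_marker If `TRUE` (quadratic model only) returns a `3 x 3`
#'   matrix of per-marker, per-direction drifts instead of drifts of the
#'   marker-averaged estimate.
#' @param invert_breathing_sign Passed to phase-linear prediction.
#' @return Named numeric vector of per-direction drifts in mm (or a
#'   `3 x 3` matrix when `per_marker = TRUE`).
#' @export
target_drift <- function(model, scan_a, scan_b, T_C, anchor = c("scan_a", "scan_b"),
                         bd_ir = NULL, per_marker = FALSE,
                         invert_breathing_sign = FALSE) {
  anchor <- match.arg(anchor)
  if (is.null(bd_ir)) {
    bd_ir <- vapply(1:3, function(i) surrogate_drift(scan_a, scan_b, i, T_C), numeric(1))
  }
  # Both medians use the predecessor-trimmed window so the anchoring
  # identity median(corrected) == anchor median holds exactly.
  wb <- tail_window(split_sessions(scan_b), T_C, scan_b$dt, need_predecessor = TRUE)
  anchor_term <- if (inherits(model, "rm_phase_linear_model")) {
    model$centroid
  } else if (anchor == "scan_a") {
    wa <- tail_window(split_sessions(scan_a), T_C, scan_a$dt, need_predecessor = TRUE)
    apply(target_matrix(scan_a)[wa, , drop = FALSE], 2, median)
  } else {
    apply(target_matrix(scan_b)[wb, , drop = FALSE], 2, median)
  }
  if (per_marker) {
    if (!inherits(model, "rm_quadratic_model")) {
      err_invalid("per-marker target drift is only defined for the quadratic model")
    }
    surr <- scan_b$surrogates
    for (i in 1:3) surr[[i]]$positions <- surr[[i]]$positions - bd_ir[i]
    est <- predict_quadratic(model, surr, wb)
    bd <- t(vapply(1:3, function(i) apply(est[, , i], 2, median), numeric(3)))
    dimnames(bd) <- list(paste0("marker", 1:3), DIRECTIONS)
    sweep(bd, 2, anchor_term)
  } else {
    est <- predict_scan(model, scan_b, wb, bd_ir = bd_ir,
                        invert_breathing_sign = invert_breathing_sign)
    setNames(apply(est, 2, median) - anchor_term, DIRECTIONS)
  }
}

#' Compute a full baseline-drift correction between two scans
#'
#' Bundles the per-marker surrogate drifts and the per-direction target
#' drift for a given correction period, with provenance so the correction
#' can only be applied to the model/scan pair it was computed for. For the
#' quadratic model the constraint `T_C <= T_M` is enforced.
#'
#' @inheritParams target_drift
#' @param per_marker_target_drift Compute and apply target drift per
#'   marker before averaging (quadratic model only).
#' @return An object of class `rm_drift_correction`.
#' @export
compute_drift_correction <- function(model, scan_a, scan_b, T_C,
                                     anchor = c("scan_a", "scan_b"),
                                     per_marker_target_drift = FALSE,
                                     invert_breathing_sign = FALSE) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(scan_a, "rm_scan"), inherits(scan_b, "rm_scan"))
  if (inherits(model, "rm_quadratic_model") && T_C > model$T_M + 1e-9) {
    err_invalid(sprintf("T_C = %g s exceeds the model's T_M = %g s", T_C, model$T_M))
  }
  if (!identical(model$source_scan_id, scan_a$scan_id)) {
    err_invalid("model was not fitted on scan_a")
  }
  bd_ir <- vapply(1:3, function(i) surrogate_drift(scan_a, scan_b, i, T_C), numeric(1))
  bd_target <- target_drift(model, scan_a, scan_b, T_C, anchor = anchor, bd_ir = bd_ir,
                            per_marker = per_marker_target_drift,
                            invert_breathing_sign = invert_breathing_sign)
  structure(
    list(bd_ir = setNames(bd_ir, paste0("marker", 1:3)), bd_target = bd_target,
         T_C = T_C, anchor = anchor, model_kind = model_kind(model),
         model_T_M = if (inherits(model, "rm_quadratic_model")) model$T_M else NA_real_,
         scan_a_id = scan_a$scan_id, scan_b_id = scan_b$scan_id,
         per_marker = per_marker_target_drift),
    class = "rm_drift_correction"
  )
}

#' @export
print.rm_drift_correction <- function(x, ...) {
  cat(sprintf("<rm_drift_correction>  T_C = %g s, anchor = %s (%s model, %s -> %s)\n",
              x$T_C, x$anchor, x$model_kind, x$scan_a_id, x$scan_b_id))
  cat(sprintf("  surrogate drift (mm): %s\n", paste(sprintf("%.2f", x$bd_ir), collapse = ", ")))
  if (is.matrix(x$bd_target)) {
    cat("  target drift per marker (mm):\n"); print(round(x$bd_target, 2))
  } else {
    cat(sprintf("  target drift LR/SI/AP (mm): %s\n",
                paste(sprintf("%.2f", x$bd_target), collapse = ", ")))
  }
  invisible(x)
}

#' Apply a drift-corrected model to a scan
#'
#' Evaluates the model on scan B's surrogate corrected by the per-marker
#' surrogate drifts and subtracts the target drift: the fully corrected
#' estimate. Marker averaging happens after per-marker prediction (and, in
#' the per-marker drift variant, after per-marker drift subtraction).
#'
#' @param model The model the correction was computed for.
#' @param scan_b The estimation target scan.
#' @param correction An `rm_drift_correction` from
#'   [compute_drift_correction()] for the same model and scan pair.
#' @param indices Sample indices of scan B to estimate (all >= 2).
#' @param invert_breathing_sign Passed to phase-linear prediction.
#' @return Numeric matrix `[length(indices), 3]`, columns LR/SI/AP (mm).
#' @export
apply_corrected <- function(model, scan_b, correction, indices,
                            invert_breathing_sign = FALSE) {
  stopifnot(inherits(correction, "rm_drift_correction"))
  if (!identical(correction$model_kind, model_kind(model)) ||
      !identical(correction$scan_a_id, model$source_scan_id) ||
      !identical(correction$scan_b_id, scan_b$scan_id) ||
      (correction$model_kind == "quadratic" &&
       !isTRUE(all.equal(correction$model_T_M, model$T_M)))) {
    err_invalid("drift correction provenance does not match this model/scan pair")
  }
  if (correction$per_marker) {
    surr <- scan_b$surrogates
    for (i in 1:3) surr[[i]]$positions <- surr[[i]]$positions - correction$bd_ir[i]
    est <- predict_quadratic(model, surr, indices)
    for (i in 1:3) est[, , i] <- sweep(est[, , i], 2, correction$bd_target[i, ])
    average_over_markers(est)
  } else {
    est <- predict_scan(model, scan_b, indices, bd_ir = correction$bd_ir,
                        invert_breathing_sign = invert_breathing_sign)
    sweep(est, 2, correction$bd_target)
  }
}
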