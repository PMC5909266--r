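COEF_NAMES <- c("a", "b", "c", "d", "e")

#' Surrogate feature vector at one sample
#'
#' The regressor vector of the quadratic estimation model:
#' `(w^2, w, 1, v^2, v)` with `v = (w_k - w_{k-1}) / dt` in mm/s. The dot
#' product of a coefficient vector `(a, b, c, d, e)` with this feature
#' vector yields a target position in mm.
#'
#' @param w_k Surrogate position at the current sample (mm).
#' @param w_km1 Surrogate position at the previous sample (mm).
#' @param dt Sampling interval (s).
#' @return Named numeric vector `(w2, w, one, v2, v)`.
#' @export
feature_vector <- function(w_k, w_km1, dt) {
  if (!is_scalar_number(w_k) || !is_scalar_number(w_km1)) err_invalid("positions must be finite")
  if (!is_scalar_number(dt) || dt <= 0) err_invalid("dt must be > 0")
  v <- (w_k - w_km1) / dt
  c(w2 = w_k^2, w = w_k, one = 1, v2 = v^2, v = v)
}

# Feature rows for `indices` of a position vector; every index needs a
# predecessor sample (index >= 2).
feature_matrix <- function(positions, indices, dt) {
  if (any(indices < 2L)) err_invalid("feature computation needs a predecessor sample (index >= 2)")
  if (any(indices > length(positions))) err_invalid("index beyond end of trace")
  w <- positions[indices]
  v <- (w - positions[indices - 1L]) / dt
  cbind(w2 = w^2, w = w, one = 1, v2 = v^2, v = v)
}

# Minimum-norm least squares via rank-revealing SVD.
# Raises a degenerate-fit error when numerical rank < 2 and warns when the
# design matrix condition number exceeds 1e8.
ls_minnorm <- function(X, Y) {
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > tol)
  if (r < 2) {
    err_degenerate_fit(sprintf(
      "design matrix has numerical rank %d (< 2); surrogate trace carries no usable motion", r))
  }
  cond <- sv$d[1] / sv$d[min(ncol(X), length(sv$d))]
  if (!is.finite(cond) || cond > 1e8) {
    warn_illconditioned(sprintf(
      "design matrix is ill-conditioned (condition number %.3g); minimum-norm solution returned",
      cond))
  }
  ur <- sv$u[, seq_len(r), drop = FALSE]
  vr <- sv$v[, seq_len(r), drop = FALSE]
  vr %*% (crossprod(ur, Y) / sv$d[seq_len(r)])
}

#' Fit the quadratic estimation equation for one marker and direction
#'
#' Least-squares fit of target position on the surrogate feature vector
#' `(w^2, w, 1, v^2, v)` over the last `T_M` seconds of the modeling
#' session. The minimum-norm solution is returned when the design matrix is
#' rank deficient (with a warning once the condition number exceeds 1e8); a
#' degenerate-fit error is raised when the numerical rank falls below 2.
#'
#' @param scan An `rm_scan`.
#' @param marker_id Marker number (1..3).
#' @param direction One of `"LR"`, `"SI"`, `"AP"`.
#' @param T_M Modeling period in seconds.
#' @param window Optional explicit integer index vector overriding the
#'   `T_M`-derived training window (all indices must have predecessors).
#' @return Named numeric coefficient vector `(a, b, c, d, e)`.
#' @export
fit_quadratic <- function(scan, marker_id, direction, T_M, window = NULL) {
  stopifnot(inherits(scan, "rm_scan"))
  direction <- match.arg(direction, DIRECTIONS)
  if (is.null(window)) {
    window <- tail_window(split_sessions(scan), T_M, scan$dt, need_predecessor = TRUE)
  }
  X <- feature_matrix(scan$surrogates[[marker_id]]$positions, window, scan$dt)
  y <- target_matrix(scan)[window, direction]
  setNames(drop(ls_minnorm(X, y)), COEF_NAMES)
}

#' Fit the full quadratic model (3 markers x 3 directions)
#'
#' @inheritParams fit_quadratic
#' @return An object of class `rm_quadratic_model` holding a
#'   `3 x 3 x 5` coefficient array (marker, direction, coefficient), the
#'   modeling period `T_M` and the source scan id.
#' @export
fit_quadratic_model <- function(scan, T_M, window = NULL) {
  stopifnot(inherits(scan, "rm_scan"))
  if (is.null(window)) {
    split <- split_sessions(scan)
    m <- period_steps(T_M, scan$dt)
    if (m <= length(split$modeling)) {
      window <- tail_window(split, T_M, scan$dt, need_predecessor = TRUE)
    } else if (m >= scan$n_samples - 1L) {
      # Whole-scan comparator fit (e.g. T_M = 70 s): validating data are
      # deliberately included in training, as in the reference workflow.
      window <- seq.int(2L, scan$n_samples)
    } else {
      err_invalid(sprintf("T_M = %g s exceeds the modeling session but is not a whole-scan fit", T_M))
    }
  }
  coeffs <- array(NA_real_, dim = c(3, 3, 5),
                  dimnames = list(paste0("marker", 1:3), DIRECTIONS, COEF_NAMES))
  Y <- target_matrix(scan)[window, , drop = FALSE]
  for (i in 1:3) {
    X <- feature_matrix(scan$surrogates[[i]]$positions, window, scan$dt)
    coeffs[i, , ] <- t(ls_minnorm(X, Y))
  }
  structure(
    list(coeffs = coeffs, T_M = T_M, source_scan_id = scan$scan_id, dt = scan$dt),
    class = "rm_quadratic_model"
  )
}

#' @export
print.rm_quadratic_model <- function(x, ...) {
  cat(sprintf("<rm_quadratic_model>  T_M = %g s, fitted on scan '%s'\n", x$T_M, x$source_scan_id))
  cat("  marker-1 coefficients (a, b, c, d, e) per direction:\n")
  print(round(x$coeffs[1, , ], 4))
  invisible(x)
}

#' Per-marker target estimates from a quadratic model
#'
#' Evaluates `C . W(t_k)` for every marker and direction at the requested
#' sample indices. Every index must have a predecessor sample (velocity).
#'
#' @param model An `rm_quadratic_model`.
#' @param surrogates List of three surrogate traces (ordered marker 1..3).
#' @param indices Integer sample indices (all >= 2).
#' @return Numeric array `[length(indices), 3 directions, 3 markers]` (mm).
#' @export
predict_quadratic <- function(model, surrogates, indices) {
  stopifnot(inherits(model, "rm_quadratic_model"))
  indices <- as.integer(indices)
  if (length(indices) == 0L) err_invalid("no indices requested")
  est <- array(NA_real_, dim = c(length(indices), 3, 3),
               dimnames = list(NULL, DIRECTIONS, paste0("marker", 1:3)))
  for (i in 1:3) {
    X <- feature_matrix(surrogates[[i]]$positions, indices, model$dt)
    est[, , i] <- X %*% t(model$coeffs[i, , ])
  }
  est
}

#' Average per-marker estimates into a single 3D estimate
#'
#' The final estimated target position is the unweighted mean of the three
#' per-marker estimates.
#'
#' @param est Array `[n, 3 directions, 3 markers]` as returned by
#'   [predict_quadratic()].
#' @return Numeric matrix `[n, 3]` with columns LR, SI, AP (mm).
#' @export
average_over_markers <- function(est) {
  if (!(is.array(est) && length(dim(est)) == 3 && dim(est)[3] == 3)) {
    err_invalid("expected an [n, 3, 3] per-marker estimate array")
  }
  out <- (est[, , 1] + est[, , 2] + est[, , 3]) / 3
  out <- matrix(out, ncol = 3, dimnames = list(NULL, DIRECTIONS))
  out
}

#' Fit the eight-phase piecewise-linear comparator model
#'
#' From eight phase-averaged surrogate positions `w_ave(l)` and eight
#' phase-averaged 3D target positions (phase 0 = end-exhalation, phase 4 =
#' end-inhalation), builds one line per adjacent phase pair
#' `(0,1), (1,2), ..., (7,0)` and per direction, plus the centroid of the
#' eight target positions (the model's baseline for drift correction).
#'
#' @param w_ave Numeric vector of 8 phase-averaged surrogate positions (mm).
#' @param p_4dcbct Numeric `8 x 3` matrix of phase-averaged target
#'   positions (mm), columns LR/SI/AP.
#' @param source_scan_id Optional id of the scan the averages came from.
#' @return An object of class `rm_phase_linear_model`.
#' @export
fit_phase_linear <- function(w_ave, p_4dcbct, source_scan_id = NA_character_) {
  w_ave <- as.numeric(w_ave)
  p_4dcbct <- as.matrix(p_4dcbct)
  if (length(w_ave) != 8 || !all(is.finite(w_ave))) err_invalid("w_ave must be 8 finite values")
  if (!all(dim(p_4dcbct) == c(8, 3)) || !all(is.finite(p_4dcbct))) {
    err_invalid("p_4dcbct must be a finite 8 x 3 matrix")
  }
  colnames(p_4dcbct) <- DIRECTIONS
  alpha <- 0:7
  beta <- c(1:7, 0)
  dw <- w_ave[beta + 1] - w_ave[alpha + 1]
  if (any(dw == 0)) {
    err_degenerate_branch(sprintf(
      "phase branches (%s) have identical surrogate positions",
      paste(sprintf("%d,%d", alpha[dw == 0], beta[dw == 0]), collapse = "; ")))
  }
  slopes <- (p_4dcbct[beta + 1, , drop = FALSE] - p_4dcbct[alpha + 1, , drop = FALSE]) / dw
  intercepts <- p_4dcbct[alpha + 1, , drop = FALSE] - slopes * w_ave[alpha + 1]
  dimnames(slopes) <- dimnames(intercepts) <-
    list(sprintf("(%d,%d)", alpha, beta), DIRECTIONS)
  structure(
    list(w_ave = w_ave, p_4dcbct = p_4dcbct, alpha = alpha, beta = beta,
         slopes = slopes, intercepts = intercepts,
         centroid = colMeans(p_4dcbct), source_scan_id = source_scan_id),
    class = "rm_phase_linear_model"
  )
}

#' @export
print.rm_phase_linear_model <- function(x, ...) {
  cat(sprintf("<rm_phase_linear_model>  8 phases, fitted on scan '%s'\n", x$source_scan_id))
  cat(sprintf("  w_ave (mm): %s\n", paste(sprintf("%.2f", x$w_ave), collapse = ", ")))
  cat(sprintf("  centroid (mm): %s\n", paste(sprintf("%.2f", x$centroid), collapse = ", ")))
  invisible(x)
}

#' Predict target position from the phase-linear model
#'
#' The breathing limb is chosen from the sign of the surrogate velocity:
#' with the printed convention, `v > 0` selects the exhalation-limb
#' branches (4,5)...(7,0) and `v < 0` the inhalation-limb branches
#' (0,1)...(3,4); zero velocity is treated as the exhalation limb. Set
#' `invert_breathing_sign = TRUE` to flip the convention (the AP axis
#' orientation is site-dependent). Within the limb, the branch whose
#' surrogate interval (min/max of its two endpoint `w_ave` values) contains
#' `w` is evaluated; out-of-range positions use the nearest branch of the
#' limb, extrapolating its line.
#'
#' @param model An `rm_phase_linear_model`.
#' @param w Numeric vector of surrogate positions (mm).
#' @param v Numeric vector of surrogate velocities (mm/s), same length.
#' @param invert_breathing_sign Flip the velocity-sign/limb convention.
#' @return Numeric matrix `[length(w), 3]`, columns LR/SI/AP (mm).
#' @export
predict_phase_linear <- function(model, w, v, invert_breathing_sign = FALSE) {
  stopifnot(inherits(model, "rm_phase_linear_model"))
  if (length(w) != length(v)) err_invalid("w and v must have the same length")
  exhal_branches <- 5:8  # (4,5), (5,6), (6,7), (7,0)
  inhal_branches <- 1:4  # (0,1), (1,2), (2,3), (3,4)
  lo <- pmin(model$w_ave[model$alpha + 1], model$w_ave[model$beta + 1])
  hi <- pmax(model$w_ave[model$alpha + 1], model$w_ave[model$beta + 1])
  out <- matrix(NA_real_, nrow = length(w), ncol = 3, dimnames = list(NULL, DIRECTIONS))
  for (k in seq_along(w)) {
    exhal <- v[k] >= 0
    if (invert_breathing_sign) exhal <- !exhal
    limb <- if (exhal) exhal_branches else inhal_branches
    inside <- limb[w[k] >= lo[limb] & w[k] <= hi[limb]]
    j <- if (length(inside) > 0) {
      inside[1]
    } else {
      # clamp: nearest branch of the limb, extrapolated
      d <- pmax(lo[limb] - w[k], w[k] - hi[limb], 0)
      limb[which.min(d)]
    }
    out[k, ] <- model$slopes[j, ] * w[k] + model$intercepts[j, ]
  }
  out
}

# Marker-averaged estimate from either model kind over scan indices,
# optionally with per-marker surrogate baseline offsets already removed.
predict_scan <- function(model, scan, indices, bd_ir = c(0, 0, 0),
                         invert_breathing_sign = FALSE) {
  surr <- scan$surrogates
  for (i in 1:3) surr[[i]]$positions <- surr[[i]]$positions - bd_ir[i]
  if (inherits(model, "rm_quadratic_model")) {
    average_over_markers(predict_quadratic(model, surr, indices))
  } else if (inherits(model, "rm_phase_linear_model")) {
    indices <- as.integer(indices)
    if (any(indices < 2L)) err_invalid("phase-linear prediction needs a predecessor sample")
    wm <- (surr[[1]]$positions + surr[[2]]$positions + surr[[3]]$positions) / 3
    w <- wm[indices]
    v <- (w - wm[indices - 1L]) / scan$dt
    predict_phase_linear(model, w, v, invert_breathing_sign)
  } else {
    err_invalid("unknown model kind")
  }
}

model_kind <- function(model) {
  if (inherits(model, "rm_quadratic_model")) "quadratic"
  else if (inherits(model, "rm_phase_linear_model")) "phase_linear"
  else err_invalid("unknown model kind")
}
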