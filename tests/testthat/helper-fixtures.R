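# Shared fixture builders. Everything is generated in code; no stored data.

# A scan whose three markers carry the same two-tone (4 s + 7 s) waveform
# scaled per marker: well-conditioned for the quadratic fit.
two_tone_scan <- function(n = 351, dt = 0.2, scales = c(1, 1, 1), noise = 0,
                          truth_coeffs = NULL, target_noise = 0, seed = 99,
                          scan_id = "twotone") {
  set.seed(seed)
  t <- (0:(n - 1)) * dt
  w0 <- 3 * sin(2 * pi * t / 4) + 1.2 * sin(2 * pi * t / 7 + 0.5) + 4
  surr <- lapply(1:3, function(i) {
    new_surrogate_trace(i, scales[i] * w0 + rnorm(n, 0, noise), dt)
  })
  if (is.null(truth_coeffs)) {
    truth_coeffs <- rbind(
      LR = c(0.004, 0.25, 1.0, 0.002, 0.05),
      SI = c(0.015, 1.80, -2.0, 0.008, 0.30),
      AP = c(0.008, 0.70, 0.5, 0.004, 0.15)
    )
  }
  truth <- coupling_truth(coeffs = truth_coeffs, target_noise_sd = target_noise)
  targ <- simulate_target(surr, truth, dt, seed = seed + 1)
  list(scan = new_scan(scan_id, surr, targ), truth = truth)
}

# Default noiseless simulator scan with identical markers (exact per-marker
# coefficient recovery is well defined).
noiseless_sim_scan <- function(seed = 42, marker_amplitudes = c(8, 8, 8),
                               target_noise = 0, scan_id = "sim") {
  params <- breathing_params(surrogate_noise_sd = 0,
                             marker_amplitudes = marker_amplitudes)
  truth <- coupling_truth(target_noise_sd = target_noise)
  surr <- simulate_surrogate(params, seed = seed)
  targ <- simulate_target(surr, truth, seed = seed + 1)
  list(scan = new_scan(scan_id, surr, targ), truth = truth, params = params)
}

# Linear-in-w coupling truth (no quadratic terms): the regime in which
# baseline shifts act as pure offsets on the target.
linear_truth <- function(target_noise = 0) {
  cc <- cbind(a = c(0, 0, 0), b = c(0.3, 1.8, 0.7), c = c(1, -2, 0.5),
              d = c(0, 0, 0), e = c(0.05, 0.3, 0.15))
  rownames(cc) <- c("LR", "SI", "AP")
  coupling_truth(coeffs = cc, target_noise_sd = target_noise)
}

# Pure-shift scan pair: identical breathing phase, zero noise, surrogate
# shifted by `s_shift`, target additionally shifted by `t_shift`.
pure_shift_pair <- function(s_shift = 3, t_shift = c(2, 2, 2), seed = 7) {
  params <- breathing_params(surrogate_noise_sd = 0, marker_amplitudes = c(8, 8, 8))
  simulate_scan_pair(params, linear_truth(), surrogate_shift = s_shift,
                     target_shift = t_shift, shared_phase = TRUE, seed = seed)
}

# Independent from-scratch oracle for the surrogate/target drift medians
# (reimplements the published window-median definitions directly).
oracle_drift <- function(model, scan_a, scan_b, T_C, anchor) {
  dt <- scan_a$dt
  win <- function(n) {
    w <- seq.int(n %/% 2 - round(T_C / dt) + 1, n %/% 2)
    w[w >= 2]
  }
  wa <- win(n_samples(scan_a)); wb <- win(n_samples(scan_b))
  bd_ir <- sapply(1:3, function(i) {
    median(scan_b$surrogates[[i]]$positions[wb]) -
      median(scan_a$surrogates[[i]]$positions[wa])
  })
  pred <- matrix(0, length(wb), 3)
  for (i in 1:3) {
    w <- scan_b$surrogates[[i]]$positions - bd_ir[i]
    v <- (w[wb] - w[wb - 1]) / dt
    X <- cbind(w[wb]^2, w[wb], 1, v^2, v)
    pred <- pred + X %*% t(model$coeffs[i, , ]) / 3
  }
  anchor_med <- if (anchor == "scan_a") {
    apply(target_matrix(scan_a)[wa, ], 2, median)
  } else {
    apply(target_matrix(scan_b)[wb, ], 2, median)
  }
  list(bd_ir = bd_ir, bd_target = apply(pred, 2, median) - anchor_med)
}
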