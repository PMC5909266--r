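test_that("surrogate drift is a difference of window medians", {
  # hand-constructed windows: medians 2.5 and 6.5 -> drift 4.0
  n <- 8; dt <- 1
  make <- function(vals) {
    surr <- lapply(1:3, function(i) new_surrogate_trace(i, vals, dt))
    targ <- new_target_trace(matrix(0:(n - 1), n, 3), dt)
    new_scan(paste0("s", vals[1]), surr, targ)
  }
  a <- make(c(1, 2, 3, 4, 9, 9, 9, 9))   # modeling = first 4 samples
  b <- make(c(2, 3, 10, 11, 9, 9, 9, 9))
  expect_equal(surrogate_drift(a, b, 1, 4), 6.5 - 2.5)
  expect_equal(surrogate_drift(a, a, 1, 4), 0)
  # shift equivariance
  b2 <- make(c(1, 2, 3, 4, 9, 9, 9, 9) + 2)
  expect_equal(surrogate_drift(a, b2, 2, 4), 2)
})

test_that("surrogate correction shifts positions, preserves velocities, round-trips", {
  tr <- new_surrogate_trace(1, sin(1:100), 0.2)
  expect_equal(correct_surrogate(tr, 0), tr)
  tr2 <- correct_surrogate(tr, 1.5)
  expect_equal(diff(tr2$positions), diff(tr$positions))
  expect_equal(correct_surrogate(tr2, -1.5), tr)
})

test_that("target drift captures constant offsets and honours the anchor", {
  fx <- noiseless_sim_scan()
  sc <- fx$scan
  model <- fit_quadratic_model(sc, 10)
  # perfect model, identical scans: zero drift in every direction
  bd <- target_drift(model, sc, sc, 10)
  expect_lt(max(abs(bd)), 1e-9)
  # predictions offset by a constant 1.5 mm: drift = 1.5 per direction
  model_off <- model
  model_off$coeffs[, , "c"] <- model_off$coeffs[, , "c"] + 1.5
  bd_off <- target_drift(model_off, sc, sc, 10)
  expect_equal(unname(bd_off), rep(1.5, 3), tolerance = 1e-9)
})

test_that("pure-shift pair: drift pipeline matches the from-scratch oracle", {
  pair <- pure_shift_pair(s_shift = 3, t_shift = c(2, 2, 2))
  model <- fit_quadratic_model(pair$scan_a, 10)
  for (anchor in c("scan_a", "scan_b")) {
    corr <- compute_drift_correction(model, pair$scan_a, pair$scan_b, 10, anchor = anchor)
    oracle <- oracle_drift(model, pair$scan_a, pair$scan_b, 10, anchor)
    expect_equal(unname(corr$bd_ir), oracle$bd_ir, tolerance = 1e-9)
    expect_equal(unname(corr$bd_target), unname(oracle$bd_target), tolerance = 1e-9)
  }
  # with anchor = scan_b the full target baseline change is captured: the
  # coupling propagates the 3 mm surrogate shift as 3b per direction, on
  # top of the injected 2 mm target shift, and the corrected-surrogate
  # estimates sit low by exactly that amount
  corr_b <- compute_drift_correction(model, pair$scan_a, pair$scan_b, 10, anchor = "scan_b")
  b_lin <- c(0.3, 1.8, 0.7)
  expect_equal(unname(corr_b$bd_target), -(3 * b_lin + 2), tolerance = 1e-9)
  expect_equal(unname(corr_b$bd_ir), rep(3, 3), tolerance = 1e-12)
})

test_that("zero-drift neutrality and shift equivariance of corrected estimates", {
  fx <- noiseless_sim_scan(seed = 8, marker_amplitudes = c(8, 7, 9))
  sc <- fx$scan
  model <- fit_quadratic_model(sc, 15)
  val <- split_sessions(sc)$validating
  corr <- compute_drift_correction(model, sc, sc, 10)
  est_cor <- apply_corrected(model, sc, corr, val)
  est_unc <- average_over_markers(predict_quadratic(model, sc$surrogates, val))
  expect_lt(max(abs(est_cor - est_unc)), 1e-9)

  # adding a constant to scan B's surrogate changes bd_ir by that constant
  # and leaves corrected estimates unchanged
  sc_shift <- sc
  sc_shift$scan_id <- "shifted"
  for (i in 1:3) sc_shift$surrogates[[i]]$positions <- sc$surrogates[[i]]$positions + 4.2
  corr2 <- compute_drift_correction(model, sc, sc_shift, 10)
  expect_equal(unname(corr2$bd_ir), unname(corr$bd_ir) + 4.2, tolerance = 1e-12)
  est2 <- apply_corrected(model, sc_shift, corr2, val)
  expect_lt(max(abs(est2 - est_cor)), 1e-8)
})

test_that("median anchoring identity holds exactly (verbatim scan-A anchor)", {
  pair <- pure_shift_pair()
  model <- fit_quadratic_model(pair$scan_a, 10)
  corr <- compute_drift_correction(model, pair$scan_a, pair$scan_b, 10, anchor = "scan_a")
  wb <- tail_window(split_sessions(pair$scan_b), 10, 0.2, need_predecessor = TRUE)
  wa <- tail_window(split_sessions(pair$scan_a), 10, 0.2, need_predecessor = TRUE)
  est <- apply_corrected(model, pair$scan_b, corr, wb)
  expect_equal(apply(est, 2, median),
               apply(target_matrix(pair$scan_a)[wa, ], 2, median),
               tolerance = 1e-12)
})

test_that("drift correction enforces T_C <= T_M and provenance", {
  pair <- pure_shift_pair()
  model <- fit_quadratic_model(pair$scan_a, 10)
  expect_error(compute_drift_correction(model, pair$scan_a, pair$scan_b, 15),
               class = "rm_invalid_input")
  corr <- compute_drift_correction(model, pair$scan_a, pair$scan_b, 5)
  other <- fit_quadratic_model(pair$scan_a, 35)
  expect_error(apply_corrected(other, pair$scan_b, corr, 200:210),
               class = "rm_invalid_input")
  expect_error(apply_corrected(model, pair$scan_a, corr, 200:210),
               class = "rm_invalid_input")
})

test_that("per-marker target drift variant averages to the corrected estimate", {
  pair <- pure_shift_pair()
  model <- fit_quadratic_model(pair$scan_a, 10)
  val <- split_sessions(pair$scan_b)$validating
  corr_pm <- compute_drift_correction(model, pair$scan_a, pair$scan_b, 10,
                                      anchor = "scan_b", per_marker_target_drift = TRUE)
  expect_true(is.matrix(corr_pm$bd_target))
  est_pm <- apply_corrected(model, pair$scan_b, corr_pm, val)
  # identical markers: per-marker and averaged variants coincide
  corr_av <- compute_drift_correction(model, pair$scan_a, pair$scan_b, 10, anchor = "scan_b")
  est_av <- apply_corrected(model, pair$scan_b, corr_av, val)
  expect_lt(max(abs(est_pm - est_av)), 1e-9)
})
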