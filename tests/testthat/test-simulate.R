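test_that("simulator is deterministic under a fixed seed", {
  params <- breathing_params()
  s1 <- simulate_surrogate(params, seed = 77)
  s2 <- simulate_surrogate(params, seed = 77)
  expect_identical(s1, s2)
  t1 <- simulate_target(s1, coupling_truth(), seed = 78)
  t2 <- simulate_target(s2, coupling_truth(), seed = 78)
  expect_identical(t1, t2)
  c1 <- simulate_cohort(3, seed = 5)
  c2 <- simulate_cohort(3, seed = 5)
  expect_identical(c1, c2)
})

test_that("noiseless simulator round trip recovers the drawn period", {
  params <- breathing_params(mean_period = 6, period_sd = 0, surrogate_noise_sd = 0,
                             amplitude_sd_frac = 0)
  surr <- simulate_surrogate(params, seed = 9)
  cyc <- detect_extrema(surr[[2]])
  expect_equal(respiratory_period(cyc), 6, tolerance = 0.2)
})

test_that("apnea suppresses breathing extrema inside its span", {
  params <- breathing_params(surrogate_noise_sd = 0)
  ev <- list(irregularity_event("apnea", start = 30, duration = 10, magnitude = 0))
  surr <- simulate_surrogate(params, events = ev, seed = 10)
  cyc <- detect_extrema(surr[[1]])
  t_inh <- (cyc$end_inhalation - 1) * 0.2
  expect_false(any(t_inh > 31 & t_inh < 39))
  # outside the event breathing continues
  expect_gt(sum(t_inh < 30 | t_inh > 40), 5)
})

test_that("event validation rejects overlap and out-of-scan spans", {
  expect_error(simulate_surrogate(breathing_params(), events = list(
    irregularity_event("apnea", 65, 10, 0)), seed = 1), class = "rm_invalid_input")
  expect_error(simulate_surrogate(breathing_params(), events = list(
    irregularity_event("apnea", 10, 10, 0),
    irregularity_event("hyperpnea", 15, 10, 2)), seed = 1),
    class = "rm_invalid_input")
})

test_that("hysteresis: nonzero velocity coefficient opens a loop in the w-P plane", {
  params <- breathing_params(period_sd = 0, amplitude_sd_frac = 0, surrogate_noise_sd = 0)
  cc_hyst <- cbind(a = rep(0, 3), b = rep(1, 3), c = rep(0, 3),
                   d = rep(0, 3), e = c(0.5, 0.5, 0.5))
  rownames(cc_hyst) <- DIRECTIONS
  surr <- simulate_surrogate(params, seed = 11)
  targ <- simulate_target(surr, coupling_truth(coeffs = cc_hyst, target_noise_sd = 0))
  # shoelace loop area over one cycle
  w <- surr[[1]]$positions[11:30]
  p <- targ$positions[11:30, "SI"]
  area <- abs(sum(w * c(p[-1], p[1]) - c(w[-1], w[1]) * p)) / 2
  expect_gt(area, 0.5)
  # without velocity terms the loop closes
  cc_flat <- cc_hyst; cc_flat[, "e"] <- 0
  targ0 <- simulate_target(surr, coupling_truth(coeffs = cc_flat, target_noise_sd = 0))
  p0 <- targ0$positions[11:30, "SI"]
  area0 <- abs(sum(w * c(p0[-1], p0[1]) - c(w[-1], w[1]) * p0)) / 2
  expect_lt(area0, 1e-9)
})

test_that("correlation-change events raise the corrected inter-scan RMSE", {
  r_event <- r_plain <- numeric(10)
  for (s in 1:10) {
    params <- breathing_params()
    truth <- coupling_truth()
    ev <- list(irregularity_event("correlation_change", 45, 20, magnitude = 0.4))
    pair_ev <- simulate_scan_pair(params, truth, events_b = ev, seed = 3000 + s)
    pair_pl <- simulate_scan_pair(params, truth, seed = 3000 + s)
    r_event[s] <- inter_scan(pair_ev$scan_a, pair_ev$scan_b, T_M = 10, T_C = 10,
                             corrected = TRUE)$rmse_3d
    r_plain[s] <- inter_scan(pair_pl$scan_a, pair_pl$scan_b, T_M = 10, T_C = 10,
                             corrected = TRUE)$rmse_3d
  }
  expect_gt(median(r_event), median(r_plain))
})

test_that("scan pairs recover the injected shifts through the drift pipeline", {
  pair <- pure_shift_pair(s_shift = 3, t_shift = c(2, 2, 2))
  for (i in 1:3) {
    expect_equal(surrogate_drift(pair$scan_a, pair$scan_b, i, 10), 3, tolerance = 1e-12)
  }
  rep <- inter_scan(pair$scan_a, pair$scan_b, T_M = 10, T_C = 10,
                    corrected = TRUE, anchor = "scan_b")
  expect_lt(rep$rmse_3d, 1e-6)
  expect_equal(rep$elapsed_min, 10.1)
})

test_that("phase averages honour linear coupling and bin geometry", {
  params <- breathing_params(surrogate_noise_sd = 0)
  surr <- simulate_surrogate(params, seed = 5)
  wm <- rowMeans(sapply(surr, function(s) s$positions))
  targ <- new_target_trace(cbind(2 * wm + 1, -wm + 3, 0.5 * wm), 0.2)
  sc <- new_scan("pl", surr, targ)
  pa <- simulate_phase_averages(sc)
  expect_length(pa$w_ave, 8)
  expect_equal(dim(pa$p_4dcbct), c(8, 3))
  expect_equal(pa$p_4dcbct[, 1], 2 * pa$w_ave + 1, tolerance = 1e-9)
  # bin 0 at end-exhalation (minimum), bin 4 at end-inhalation (maximum)
  expect_equal(which.min(pa$w_ave), 1)
  expect_equal(which.max(pa$w_ave), 5)
  # too few cycles -> error
  short <- new_scan("short",
                    lapply(surr, function(s) { s$positions <- s$positions[1:20]; s }),
                    new_target_trace(targ$positions[1:20, ], 0.2))
  expect_error(simulate_phase_averages(short), class = "rm_insufficient_cycles")
})

test_that("cohort draws fall inside the population spans and support evaluation", {
  cohort <- simulate_cohort(20, seed = 2)
  expect_length(cohort, 20)
  d <- do.call(rbind, lapply(cohort, function(e) {
    data.frame(period = e$params$mean_period,
               amp = mean(e$params$marker_amplitudes),
               elapsed = e$elapsed_min)
  }))
  expect_true(all(d$period >= 2.4 & d$period <= 13.0))
  expect_true(all(d$elapsed >= 1.7 & d$elapsed <= 15.0))
  desc <- scan_descriptors(cohort[[1]]$scan_a)
  expect_true(is.finite(desc$period_s))
  # single-patient cohort is usable end to end
  c1 <- simulate_cohort(1, seed = 3)
  g <- grid_sweep(c1, T_M_set = c(5, 10), T_C_set = 5)
  expect_equal(nrow(g$results) + g$n_failed, 2 * (2 + 2))
})

test_that("descriptor medians of a default cohort land in the printed spans", {
  cohort <- simulate_cohort(20, seed = 4)
  desc <- do.call(rbind, lapply(cohort, function(e) scan_descriptors(e$scan_a)))
  expect_gt(median(desc$period_s), 2.4)
  expect_lt(median(desc$period_s), 13.0)
  expect_gt(median(desc$marker1_amplitude_mm), 1.7)
  expect_lt(median(desc$marker1_amplitude_mm), 14.6)
  expect_gt(median(desc$target_3d_amplitude_mm, na.rm = TRUE), 2.8)
  expect_lt(median(desc$target_3d_amplitude_mm, na.rm = TRUE), 34.2)
})
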