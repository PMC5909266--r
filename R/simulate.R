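#' Breathing parameters for the simulator
#'
#' Describes one virtual patient's external breathing signal. The default
#' waveform is the cos^(2n) profile (n = 2), a standard respiratory shape
#' with an extended end-exhalation dwell; cycle periods are jittered
#' independently per cycle, amplitudes per cycle and marker.
#'
#' @param mean_period Mean respiratory period in s. The clinically observed
#'   population spans 2.4-13.0 s; values outside that span trigger a warning.
#' @param period_sd Per-cycle period jitter (standard deviation, s); draws
#'   are truncated above 1 s.
#' @param marker_amplitudes Peak-to-peak AP amplitudes of the three
#'   abdominal markers (mm); the observed population span is 1.7-14.6 mm.
#' @param amplitude_sd_frac Fractional per-cycle amplitude jitter.
#' @param waveform_exponent Positive integer n of the cos^(2n) profile.
#' @param surrogate_noise_sd Additive marker noise (mm, per sample).
#' @param drift_rate Within-scan linear baseline trend (mm/min); stress-test
#'   option, 0 by default (between-scan drift is a constant offset instead).
#' @param baseline Resting (end-exhalation) position of each marker (mm).
#' @param seed Optional RNG seed used by simulators when none is passed.
#' @return An object of class `rm_breathing_params`.
#' @export
breathing_params <- function(mean_period = 4, period_sd = 0.25,
                             marker_amplitudes = c(8, 7, 9),
                             amplitude_sd_frac = 0.05, waveform_exponent = 2,
                             surrogate_noise_sd = 0.1, drift_rate = 0,
                             baseline = c(0, 0, 0), seed = NULL) {
  if (!is_scalar_number(mean_period) || mean_period <= 1) {
    err_invalid("mean_period must be > 1 s")
  }
  if (mean_period < 2.4 || mean_period > 13.0) {
    warning("mean_period outside the clinically observed span 2.4-13.0 s")
  }
  if (length(marker_amplitudes) != 3 || any(marker_amplitudes < 0)) {
    err_invalid("marker_amplitudes must be three non-negative values")
  }
  if (!is_scalar_number(waveform_exponent) || waveform_exponent < 1 ||
      waveform_exponent != round(waveform_exponent)) {
    err_invalid("waveform_exponent must be a positive integer")
  }
  if (period_sd < 0 || amplitude_sd_frac < 0 || surrogate_noise_sd < 0) {
    err_invalid("jitter and noise parameters must be non-negative")
  }
  structure(
    list(mean_period = mean_period, period_sd = period_sd,
         marker_amplitudes = as.numeric(marker_amplitudes),
         amplitude_sd_frac = amplitude_sd_frac,
         waveform_exponent = as.integer(waveform_exponent),
         surrogate_noise_sd = surrogate_noise_sd, drift_rate = drift_rate,
         baseline = as.numeric(baseline), seed = seed),
    class = "rm_breathing_params"
  )
}

#' Ground-truth surrogate-to-target coupling
#'
#' The generative coupling from which simulated targets are built: one
#' `(a, b, c, d, e)` coefficient quintuple per marker and direction applied
#' to the feature vector `(w^2, w, 1, v^2, v)`, marker-averaged, plus
#' Gaussian target noise. Nonzero velocity coefficients d, e produce
#' hysteresis (the target leads/lags the surrogate). The defaults give a
#' strongly coupled SI direction, as observed clinically, and a 3D target
#' amplitude inside the observed 2.8-34.2 mm span for default breathing.
#'
#' @param coeffs Optional `3 x 3 x 5` array (marker, direction, coefficient);
#'   a single `3 x 5` (direction x coefficient) matrix is replicated over
#'   markers. `NULL` uses the defaults.
#' @param target_noise_sd Additive target noise (mm, per sample).
#' @param marker_heterogeneity Fractional perturbation of per-marker
#'   couplings (0 = identical markers, i.e. the estimator's marker
#'   averaging is correctly specified).
#' @param seed RNG seed for the heterogeneity draw.
#' @return An object of class `rm_coupling_truth`.
#' @export
coupling_truth <- function(coeffs = NULL, target_noise_sd = 0.5,
                           marker_heterogeneity = 0, seed = NULL) {
  if (is.null(coeffs)) {
    coeffs <- rbind(
      LR = c(a = 0.004, b = 0.25, c = 1.0, d = 0.002, e = 0.05),
      SI = c(a = 0.015, b = 1.80, c = -2.0, d = 0.008, e = 0.30),
      AP = c(a = 0.008, b = 0.70, c = 0.5, d = 0.004, e = 0.15)
    )
  }
  if (is.matrix(coeffs)) {
    if (!all(dim(coeffs) == c(3, 5))) err_invalid("coefficient matrix must be 3 x 5")
    coeffs <- aperm(array(rep(t(coeffs), 3), dim = c(5, 3, 3)), c(3, 2, 1))
  }
  if (!all(dim(coeffs) == c(3, 3, 5))) err_invalid("coeffs must be a 3 x 3 x 5 array")
  dimnames(coeffs) <- list(paste0("marker", 1:3), DIRECTIONS, COEF_NAMES)
  if (marker_heterogeneity > 0) {
    coeffs <- with_seed(seed, {
      coeffs * array(1 + marker_heterogeneity * rnorm(length(coeffs)), dim = dim(coeffs))
    })
  }
  if (target_noise_sd < 0) err_invalid("target_noise_sd must be non-negative")
  structure(
    list(coeffs = coeffs, target_noise_sd = target_noise_sd,
         marker_heterogeneity = marker_heterogeneity),
    class = "rm_coupling_truth"
  )
}

#' Describe an irregular-breathing event
#'
#' @param kind One of `"apnea"`, `"hyperpnea"`, `"hypopnea"`,
#'   `"correlation_change"`.
#' @param start Event onset in seconds from scan start.
#' @param duration Event duration in seconds.
#' @param magnitude Dimensionless factor: amplitude multiplier for the
#'   breathing-amplitude kinds (apnea ~ 0, hypopnea < 1, hyperpnea > 1), or
#'   coupling-coefficient multiplier for `"correlation_change"`.
#' @return An object of class `rm_irregularity_event`.
#' @export
irregularity_event <- function(kind = c("apnea", "hyperpnea", "hypopnea", "correlation_change"),
                               start, duration, magnitude) {
  kind <- match.arg(kind)
  if (!is_scalar_number(start) || start < 0) err_invalid("event start must be >= 0")
  if (!is_scalar_number(duration) || duration <= 0) err_invalid("event duration must be > 0")
  if (!is_scalar_number(magnitude) || magnitude < 0) err_invalid("event magnitude must be >= 0")
  structure(list(kind = kind, start = start, duration = duration, magnitude = magnitude),
            class = "rm_irregularity_event")
}

check_events <- function(events, duration) {
  if (length(events) == 0) return(invisible(NULL))
  stopifnot(all(vapply(events, inherits, logical(1), "rm_irregularity_event")))
  spans <- t(vapply(events, function(e) c(e$start, e$start + e$duration), numeric(2)))
  if (any(spans[, 2] > duration + 1e-9)) err_invalid("event extends beyond the scan duration")
  o <- order(spans[, 1])
  if (nrow(spans) > 1 && any(spans[o, 1][-1] < spans[o, 2][-nrow(spans)] - 1e-9)) {
    err_invalid("irregularity events must not overlap")
  }
  invisible(NULL)
}

event_mask <- function(events, kinds, t) {
  m <- rep(1, length(t))
  for (e in events) {
    if (e$kind %in% kinds) m[t >= e$start & t < e$start + e$duration] <- e$magnitude
  }
  m
}

# Quasi-periodic cycle structure: start times, periods and per-cycle,
# per-marker amplitude multipliers covering [0, duration], beginning at a
# uniformly random initial phase. The amplitude jitter lives here so that
# two scans sharing the structure differ only by baseline and noise.
gen_cycles <- function(params, duration, random_phase = TRUE) {
  draw <- function() {
    repeat {
      tau <- if (params$period_sd > 0) {
        rnorm(1, params$mean_period, params$period_sd)
      } else params$mean_period
      if (tau > 1) return(tau)
    }
  }
  first <- draw()
  t0 <- if (random_phase) -runif(1) * first else 0
  starts <- t0
  periods <- first
  while (starts[length(starts)] + periods[length(periods)] < duration) {
    starts <- c(starts, starts[length(starts)] + periods[length(periods)])
    periods <- c(periods, draw())
  }
  # One depth multiplier per cycle, shared by the three markers: the
  # abdominal markers breathe coherently, so per-cycle depth variation is
  # common mode (per-marker decoupling is modelled via marker_heterogeneity
  # in the coupling truth instead).
  amp_mult <- pmax(0.05, 1 + params$amplitude_sd_frac * rnorm(length(periods)))
  list(start = starts, period = periods, amp_mult = amp_mult)
}

#' Simulate the three surrogate marker traces
#'
#' Each marker follows `b0 + drift*t/60 + m(t) * A_c * cos^(2n)(pi (t - t_c)/tau_c)`
#' plus Gaussian noise, with per-cycle period and amplitude jitter shared
#' cycle structure across the three markers, and `m(t)` the amplitude
#' multiplier of any breathing-amplitude irregularity event covering `t`.
#' The cycle structure used is attached as attribute `"cycles"` so a second
#' scan can share the same breathing phase.
#'
#' @param params An [breathing_params()] object.
#' @param duration Scan duration in seconds (multiple of `dt`).
#' @param dt Sampling interval in seconds.
#' @param events List of [irregularity_event()] objects.
#' @param seed RNG seed (defaults to `params$seed`).
#' @param cycles Optional cycle structure from a previous call (shared
#'   breathing phase between scans).
#' @return List of three `rm_surrogate_trace` objects.
#' @export
simulate_surrogate <- function(params, duration = 70, dt = 0.2, events = list(),
                               seed = params$seed, cycles = NULL) {
  stopifnot(inherits(params, "rm_breathing_params"))
  n <- sample_count(duration, dt)
  check_events(events, duration)
  with_seed(seed, {
    if (is.null(cycles)) cycles <- gen_cycles(params, duration)
    t <- (0:(n - 1)) * dt
    ci <- findInterval(t, cycles$start)
    phase <- (t - cycles$start[ci]) / cycles$period[ci]
    base <- cos(pi * phase)^(2 * params$waveform_exponent)
    m <- event_mask(events, c("apnea", "hyperpnea", "hypopnea"), t)
    traces <- vector("list", 3)
    for (i in 1:3) {
      amp_c <- params$marker_amplitudes[i] * cycles$amp_mult
      w <- params$baseline[i] + params$drift_rate * t / 60 + m * amp_c[ci] * base +
        rnorm(n, 0, params$surrogate_noise_sd)
      traces[[i]] <- new_surrogate_trace(i, w, dt)
    }
    attr(traces, "cycles") <- cycles
    traces
  })
}

#' Simulate the target trace from surrogate traces
#'
#' Applies the ground-truth coupling generatively: per direction, the
#' marker average of `C_i . W_i(t_k)` plus Gaussian noise. Velocities use
#' the backward difference; the first sample uses a forward difference and
#' is therefore not usable for fitting. A `"correlation_change"` event
#' scales the motion-coupling coefficients (a, b, d, e) by its magnitude
#' over its span, emulating a sudden change in the internal-external
#' correlation.
#'
#' @param surrogates List of three surrogate traces.
#' @param truth An [coupling_truth()] object.
#' @param dt Sampling interval in seconds.
#' @param events List of [irregularity_event()] objects (only
#'   `"correlation_change"` is interpreted here).
#' @param seed Optional RNG seed.
#' @return An `rm_target_trace`.
#' @export
simulate_target <- function(surrogates, truth, dt = 0.2, events = list(), seed = NULL) {
  stopifnot(inherits(truth, "rm_coupling_truth"))
  n <- length(surrogates[[1]]$positions)
  t <- (0:(n - 1)) * dt
  with_seed(seed, {
    det_full <- matrix(0, n, 3)
    det_motion <- matrix(0, n, 3)  # contribution of (a, b, d, e) terms only
    for (i in 1:3) {
      w <- surrogates[[i]]$positions
      v <- c((w[2] - w[1]) / dt, diff(w) / dt)
      X <- cbind(w^2, w, 1, v^2, v)
      Ci <- t(truth$coeffs[i, , ])  # 5 x 3
      det_full <- det_full + X %*% Ci / 3
      det_motion <- det_motion + X[, c(1, 2, 4, 5)] %*% Ci[c(1, 2, 4, 5), ] / 3
    }
    g <- event_mask(events, "correlation_change", t)
    det <- det_full + (g - 1) * det_motion
    noise <- matrix(rnorm(3 * n, 0, truth$target_noise_sd), n, 3)
    new_target_trace(det + noise, dt)
  })
}

#' Simulate a pair of scans with baseline drift
#'
#' Scan A is drawn fresh; scan B is re-drawn with the same coupling truth,
#' its surrogate baseline shifted by `surrogate_shift` and its target
#' baseline additionally shifted by `target_shift` per direction, with
#' independent noise. The target of scan B is generated from the shifted
#' surrogate (the coupling follows the drifted surrogate), so
#' `target_shift` is the residual target baseline drift that surrogate
#' correction alone cannot remove. Timestamps are `elapsed_min` minutes
#' apart.
#'
#' @param params An [breathing_params()] object.
#' @param truth An [coupling_truth()] object.
#' @param elapsed_min Elapsed time between scans in minutes (metadata).
#' @param surrogate_shift Surrogate baseline shift of scan B (mm, all
#'   markers).
#' @param target_shift Numeric length-3 target baseline shift of scan B
#'   (mm, LR/SI/AP).
#' @param events_a,events_b Irregularity events for each scan.
#' @param shared_phase If `TRUE`, scan B reuses scan A's cycle structure
#'   (identical breathing phase).
#' @param duration,dt Scan duration and sampling interval (s).
#' @param seed RNG seed for the whole pair.
#' @param scan_ids Character ids of the two scans.
#' @return List with elements `scan_a` and `scan_b` (`rm_scan` objects).
#' @export
simulate_scan_pair <- function(params, truth, elapsed_min = 10.1,
                               surrogate_shift = 0, target_shift = c(0, 0, 0),
                               events_a = list(), events_b = list(),
                               shared_phase = FALSE, duration = 70, dt = 0.2,
                               seed = NULL, scan_ids = c("scanA", "scanB")) {
  if (length(target_shift) != 3) err_invalid("target_shift must have length 3")
  with_seed(seed, {
    surr_a <- simulate_surrogate(params, duration, dt, events = events_a, seed = NULL)
    targ_a <- simulate_target(surr_a, truth, dt, events = events_a, seed = NULL)
    scan_a <- new_scan(scan_ids[1], surr_a, targ_a, acquired_at = 0)

    params_b <- params
    params_b$baseline <- params$baseline + surrogate_shift
    surr_b <- simulate_surrogate(params_b, duration, dt, events = events_b, seed = NULL,
                                 cycles = if (shared_phase) attr(surr_a, "cycles") else NULL)
    targ_b <- simulate_target(surr_b, truth, dt, events = events_b, seed = NULL)
    targ_b$positions <- sweep(targ_b$positions, 2, -as.numeric(target_shift))
    scan_b <- new_scan(scan_ids[2], surr_b, targ_b, acquired_at = elapsed_min * 60)
    list(scan_a = scan_a, scan_b = scan_b)
  })
}

#' Phase-averaged surrogate and target positions of a scan
#'
#' Emulates respiration-sorted phase averaging: breathing cycles are
#' delimited by the end-exhalation samples of the marker-averaged
#' surrogate, each sample is assigned a phase bin by its elapsed cycle
#' fraction (round-to-nearest binning, so bin 0 is centred at
#' end-exhalation and bin 4 at end-inhalation), and per-bin means of the
#' marker-averaged surrogate and of the target are returned.
#'
#' @param scan An `rm_scan` containing at least 2 complete breathing cycles.
#' @param n_phases Number of phase bins (8 nominal).
#' @param ... Passed to [detect_extrema()].
#' @return List with `w_ave` (length `n_phases`) and `p_4dcbct`
#'   (`n_phases x 3` matrix).
#' @export
simulate_phase_averages <- function(scan, n_phases = 8, ...) {
  stopifnot(inherits(scan, "rm_scan"))
  wm <- rowMeans(surrogate_matrix(scan))
  cyc <- detect_extrema(wm, dt = scan$dt, ...)
  ee <- cyc$end_exhalation
  if (length(ee) < 3) {
    err_insufficient_cycles("need at least 2 complete breathing cycles for phase averaging")
  }
  k <- seq.int(ee[1], ee[length(ee)])
  ci <- findInterval(k, ee, rightmost.closed = TRUE)
  frac <- (k - ee[ci]) / (ee[ci + 1] - ee[ci])
  bin <- floor(frac * n_phases + 0.5) %% n_phases
  tm <- target_matrix(scan)
  w_ave <- numeric(n_phases)
  p <- matrix(NA_real_, n_phases, 3, dimnames = list(NULL, DIRECTIONS))
  for (l in 0:(n_phases - 1)) {
    sel <- k[bin == l]
    if (length(sel) == 0) {
      err_insufficient_cycles(sprintf("phase bin %d is empty; too few cycles sampled", l))
    }
    w_ave[l + 1] <- mean(wm[sel])
    p[l + 1, ] <- colMeans(tm[sel, , drop = FALSE])
  }
  list(w_ave = w_ave, p_4dcbct = p)
}

default_cohort_ranges <- function() {
  list(
    mean_period = c(2.4, 13.0),        # s, observed population span
    marker_amplitude = c(1.7, 14.6),   # mm, AP surrogate peak-to-peak
    target_amplitude_3d = c(2.8, 34.2),# mm
    elapsed_min = c(1.7, 15.0),        # min between scans
    surrogate_shift_sd = 2,            # mm, between-scan surrogate drift
    target_shift_sd = 1.5,             # mm, residual target drift per axis
    period_sd_frac = 0.06,
    amplitude_sd_frac = 0.05,
    surrogate_noise_sd = 0.1,          # mm
    target_noise_sd = 0.5              # mm
  )
}

#' Simulate a cohort of virtual patients
#'
#' Draws per-patient breathing and coupling parameters uniformly from the
#' observed population spans (period 2.4-13.0 s, surrogate amplitude
#' 1.7-14.6 mm, target 3D amplitude 2.8-34.2 mm, elapsed time between scans
#' 1.7-15.0 min) and simulates one scan pair per patient with between-scan
#' baseline drift of surrogate and target. Deterministic per seed.
#'
#' @param n_patients Number of virtual patients (>= 1).
#' @param param_ranges Named list overriding entries of the default ranges
#'   (see Details in the package vignette).
#' @param seed RNG seed.
#' @param duration,dt Scan duration and sampling interval (s).
#' @return List of cohort entries; each has `patient_id`, `params`,
#'   `truth`, `scan_a`, `scan_b`, `elapsed_min`, `surrogate_shift`,
#'   `target_shift`.
#' @export
simulate_cohort <- function(n_patients, param_ranges = list(), seed = NULL,
                            duration = 70, dt = 0.2) {
  if (!is_scalar_number(n_patients) || n_patients < 1) err_invalid("n_patients must be >= 1")
  rg <- modifyList(default_cohort_ranges(), param_ranges)
  with_seed(seed, {
    lapply(seq_len(n_patients), function(p) {
      mp <- runif(1, rg$mean_period[1], rg$mean_period[2])
      amp_base <- runif(1, rg$marker_amplitude[1], rg$marker_amplitude[2])
      amps <- amp_base * runif(3, 0.85, 1.15)
      params <- suppressWarnings(breathing_params(
        mean_period = mp, period_sd = rg$period_sd_frac * mp,
        marker_amplitudes = amps, amplitude_sd_frac = rg$amplitude_sd_frac,
        surrogate_noise_sd = rg$surrogate_noise_sd
      ))
      # Direction split of the desired 3D target amplitude: SI dominant,
      # as observed clinically; linear coefficients set so that the linear
      # term reproduces the split, with small quadratic and velocity
      # (hysteresis) terms scaled to the breathing amplitude and period.
      a3d <- runif(1, rg$target_amplitude_3d[1], rg$target_amplitude_3d[2])
      u <- c(runif(1, 0.05, 0.4), runif(1, 0.6, 1.0), runif(1, 0.2, 0.7))
      u <- u / sqrt(sum(u^2))
      b <- a3d * u / amp_base
      a <- 0.03 * b / amp_base
      e <- 0.10 * b * mp / pi
      d <- 0.02 * b * mp^2 / pi^2 / amp_base
      cc <- cbind(a = a, b = b, c = runif(3, -5, 5), d = d, e = e)
      rownames(cc) <- DIRECTIONS
      truth <- coupling_truth(coeffs = cc, target_noise_sd = rg$target_noise_sd)
      elapsed <- runif(1, rg$elapsed_min[1], rg$elapsed_min[2])
      s_shift <- rnorm(1, 0, rg$surrogate_shift_sd)
      t_shift <- rnorm(3, 0, rg$target_shift_sd)
      pid <- sprintf("P%02d", p)
      pair <- simulate_scan_pair(
        params, truth, elapsed_min = elapsed, surrogate_shift = s_shift,
        target_shift = t_shift, duration = duration, dt = dt, seed = NULL,
        scan_ids = paste0(pid, c("_scanA", "_scanB"))
      )
      list(patient_id = pid, params = params, truth = truth,
           scan_a = pair$scan_a, scan_b = pair$scan_b, elapsed_min = elapsed,
           surrogate_shift = s_shift, target_shift = t_shift)
    })
  })
}
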