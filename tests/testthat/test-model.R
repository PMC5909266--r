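test_that("feature vector matches hand arithmetic and is shift invariant in velocity", {
  expect_equal(unname(feature_vector(0, 0, 0.2)), c(0, 0, 1, 0, 0))
  expect_equal(unname(feature_vector(2, 1, 0.2)), c(4, 2, 1, 25, 5))
  f1 <- feature_vector(3.7, 2.1, 0.2)
  f2 <- feature_vector(3.7 + 10, 2.1 + 10, 0.2)
  expect_equal(f1[c("v2", "v")], f2[c("v2", "v")])
})

test_that("quadratic fit matches a normal-equations oracle on the same window", {
  fx <- two_tone_scan(target_noise = 0.3)
  sc <- fx$scan
  win <- tail_window(split_sessions(sc), 10, sc$dt, need_predecessor = TRUE)
  for (marker in c(1L, 3L)) {
    w <- sc$surrogates[[marker]]$positions
    v <- (w[win] - w[win - 1]) / sc$dt
    X <- cbind(w[win]^2, w[win], 1, v^2, v)
    for (dir in c("SI", "AP")) {
      oracle <- solve(t(X) %*% X, t(X) %*% target_matrix(sc)[win, dir])
      fit <- fit_quadratic(sc, marker, dir, 10)
      expect_equal(unname(fit), unname(drop(oracle)), tolerance = 1e-8)
    }
  }
})

test_that("identity mapping and generative coefficients are recovered noiselessly", {
  # target == surrogate AP channel: coefficients (0, 1, 0, 0, 0)
  n <- 351; dt <- 0.2; t <- (0:(n - 1)) * dt
  w0 <- 3 * sin(2 * pi * t / 4) + 1.2 * sin(2 * pi * t / 7) + 4
  surr <- lapply(1:3, function(i) new_surrogate_trace(i, w0, dt))
  targ <- new_target_trace(cbind(w0, w0, w0), dt)
  sc <- new_scan("id", surr, targ)
  fit <- fit_quadratic(sc, 1, "AP", 10)
  expect_equal(unname(fit), c(0, 1, 0, 0, 0), tolerance = 1e-6)

  # known coefficients on a two-tone surrogate
  cc <- rbind(LR = c(0.02, 0.9, 3.0, 0.01, 0.5),
              SI = c(0.02, 0.9, 3.0, 0.01, 0.5),
              AP = c(0.02, 0.9, 3.0, 0.01, 0.5))
  fx <- two_tone_scan(truth_coeffs = cc)
  fit <- fit_quadratic(fx$scan, 2, "SI", 10)
  expect_equal(unname(fit), unname(cc["SI", ]), tolerance = 1e-6)
})

test_that("constant surrogate raises a degenerate-fit error", {
  n <- 351; dt <- 0.2
  surr <- lapply(1:3, function(i) new_surrogate_trace(i, rep(5, n), dt))
  targ <- new_target_trace(matrix(rnorm(3 * n), n, 3), dt)
  sc <- new_scan("flat", surr, targ)
  expect_error(fit_quadratic(sc, 1, "SI", 10), class = "rm_degenerate_fit")
})

test_that("prediction equals the stored-coefficient dot product and refits its window", {
  fx <- two_tone_scan(scales = c(1, 0.9, 1.1))
  sc <- fx$scan
  model <- fit_quadratic_model(sc, 15)
  win <- tail_window(split_sessions(sc), 15, sc$dt, need_predecessor = TRUE)
  est <- predict_quadratic(model, sc$surrogates, win)
  # residuals on the (consistent, noiseless) training window vanish
  for (i in 1:3) {
    expect_lt(max(abs(est[, , i] - target_matrix(sc)[win, ])), 1e-9)
  }
  # brute-force dot product at 10 random indices
  set.seed(3)
  idx <- sample(2:n_samples(sc), 10)
  est2 <- predict_quadratic(model, sc$surrogates, idx)
  for (k in seq_along(idx)) {
    w <- sc$surrogates[[2]]$positions
    fv <- feature_vector(w[idx[k]], w[idx[k] - 1], sc$dt)
    for (d in DIRECTIONS) {
      expect_equal(est2[k, d, 2], sum(model$coeffs[2, d, ] * fv))
    }
  }
  expect_error(predict_quadratic(model, sc$surrogates, c(1, 5)),
               class = "rm_invalid_input")
  # constant-only model predicts its constant
  model0 <- model
  model0$coeffs[] <- 0
  model0$coeffs[, , "c"] <- 7
  est0 <- predict_quadratic(model0, sc$surrogates, 10:20)
  expect_true(all(est0 == 7))
})

test_that("marker averaging is an unweighted permutation-invariant mean", {
  est <- array(0, dim = c(4, 3, 3))
  est[, , 1] <- 1; est[, , 2] <- 2; est[, , 3] <- 3
  expect_true(all(average_over_markers(est) == 2))
  set.seed(11)
  est[] <- rnorm(length(est))
  avg <- average_over_markers(est)
  expect_equal(avg, (est[, , 1] + est[, , 2] + est[, , 3]) / 3,
               ignore_attr = TRUE)
  perm <- est[, , c(3, 1, 2)]
  expect_equal(average_over_markers(perm), avg)
})

test_that("phase-linear fit reproduces exact linear relations and the centroid", {
  w_ave <- c(0.2, 1.5, 3.9, 6.1, 7.6, 6.0, 3.8, 1.4)
  p <- cbind(2 * w_ave + 1, -0.5 * w_ave + 3, 1.3 * w_ave)
  m <- fit_phase_linear(w_ave, p)
  expect_true(all(abs(m$slopes[, 1] - 2) < 1e-12))
  expect_true(all(abs(m$intercepts[, 1] - 1) < 1e-12))
  expect_true(all(abs(m$slopes[, 2] + 0.5) < 1e-12))
  expect_equal(unname(m$centroid[1]), mean(p[, 1]))
  # centroid of a scalar ramp 0..7 is 3.5
  m2 <- fit_phase_linear(w_ave, cbind(0:7, 0:7, 0:7))
  expect_equal(unname(m2$centroid), rep(3.5, 3))
  # per-branch slopes match the two-point finite-difference oracle
  set.seed(4)
  p3 <- matrix(rnorm(24), 8, 3)
  m3 <- fit_phase_linear(w_ave, p3)
  a <- 0:7; b <- c(1:7, 0)
  for (j in 1:8) {
    expect_equal(unname(m3$slopes[j, ]),
                 (p3[b[j] + 1, ] - p3[a[j] + 1, ]) / (w_ave[b[j] + 1] - w_ave[a[j] + 1]))
  }
  expect_error(fit_phase_linear(rep(1, 8), p), class = "rm_degenerate_branch")
})

test_that("phase-linear prediction selects branches like an exhaustive oracle", {
  w_ave <- c(0.2, 1.5, 3.9, 6.1, 7.6, 6.0, 3.8, 1.4)
  set.seed(5)
  p <- cbind(2 * w_ave + 1 + rnorm(8, 0, 0.3), rnorm(8), rnorm(8))
  m <- fit_phase_linear(w_ave, p)
  # interpolation through a knot returns the knot value
  out <- predict_phase_linear(m, w_ave[3], -1)  # phase 2, inhalation limb
  expect_equal(unname(out[1, ]), unname(p[3, ]))
  # exhaustive-branch oracle over random (w, v) pairs
  lo <- pmin(w_ave[m$alpha + 1], w_ave[m$beta + 1])
  hi <- pmax(w_ave[m$alpha + 1], w_ave[m$beta + 1])
  oracle_one <- function(w, v) {
    limb <- if (v >= 0) 5:8 else 1:4
    inside <- limb[w >= lo[limb] & w <= hi[limb]]
    j <- if (length(inside)) inside[1] else limb[which.min(pmax(lo[limb] - w, w - hi[limb], 0))]
    m$slopes[j, ] * w + m$intercepts[j, ]
  }
  w <- runif(100, -1, 9); v <- runif(100, -5, 5)
  pred <- predict_phase_linear(m, w, v)
  for (k in 1:100) expect_equal(unname(pred[k, ]), unname(oracle_one(w[k], v[k])))
  # continuity within a limb: prediction through shared knots is continuous
  ws <- seq(min(w_ave), max(w_ave), length.out = 400)
  ps <- predict_phase_linear(m, ws, rep(-1, 400))[, 1]
  expect_lt(max(abs(diff(ps))), max(abs(m$slopes[, 1])) * diff(ws[1:2]) * 1.01)
  # exactly linear relation: the global line regardless of branch or limb
  mlin <- fit_phase_linear(w_ave, cbind(2 * w_ave + 1, 2 * w_ave + 1, 2 * w_ave + 1))
  out <- predict_phase_linear(mlin, c(-2, 0.7, 4.2, 9.9), c(1, -1, 1, -1))
  expect_equal(unname(out[, 1]), 2 * c(-2, 0.7, 4.2, 9.9) + 1)
  # invert_breathing_sign flips the limb choice
  p_out <- predict_phase_linear(m, 2.6, 1)
  p_inv <- predict_phase_linear(m, 2.6, -1, invert_breathing_sign = TRUE)
  expect_equal(p_out, p_inv)
})
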