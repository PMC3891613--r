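test_that("the reference shape realigns a noiseless plane wave exactly", {
  tau_r <- 0.0123; tau_c <- -0.0061
  win <- make_plane_window(tau_r = tau_r, tau_c = tau_c)
  sh <- estimate_reference_shape(win, list(tau_r_s = tau_r, tau_c_s = tau_c))
  s_hat <- Re(fft(sh$spectrum, inverse = TRUE)) / sh$n_samples
  s_true <- win$grid_segment[1, 1, ]
  expect_lt(max(abs(s_hat - s_true)) / max(abs(s_true)), 1e-6)
})

test_that("degenerate grids reduce the shape to known forms", {
  # 1x1: the shape is the channel spectrum itself
  x <- sin(2 * pi * 2 * (0:199) / 100) * exp(-(0:199 - 100)^2 / 500)
  win1 <- analysis_window(array(x, dim = c(1, 1, 200)), 100, 0.5)
  sh <- estimate_reference_shape(win1, list(tau_r_s = 0, tau_c_s = 0))
  expect_equal(sh$spectrum, as.vector(fft(x)), tolerance = 1e-12)

  # 1x2 with equal weights: arithmetic mean of realigned spectra
  set.seed(3)
  g <- array(rnorm(2 * 300), dim = c(1, 2, 300))
  win2 <- analysis_window(g, 100, 0.5)
  tc <- 0.017
  sh2 <- estimate_reference_shape(win2, list(tau_r_s = 0, tau_c_s = tc))
  f <- c(0:150, -149:-1) * 100 / 300
  oracle <- (fft(g[1, 1, ]) + fft(g[1, 2, ]) * exp(2i * pi * f * tc)) / 2
  expect_equal(sh2$spectrum, oracle, tolerance = 1e-10)
})

test_that("the cost is zero at truth and larger at perturbed delays", {
  tau_r <- 0.02; tau_c <- 0.012
  win <- make_plane_window(tau_r = tau_r, tau_c = tau_c)
  truth <- list(tau_r_s = tau_r, tau_c_s = tau_c)
  sh <- estimate_reference_shape(win, truth)
  energy <- sum(win$grid_segment^2)
  expect_lt(cost_e2(truth, win, sh), 1e-10 * energy)
  off <- list(tau_r_s = 1.5 * tau_r, tau_c_s = 1.5 * tau_c)
  expect_gt(cost_e2(off, win, sh), cost_e2(truth, win, sh))
})

test_that("the spectral cost equals the time-domain weighted SSD (Parseval)", {
  set.seed(5)
  win <- make_plane_window(tau_r = 0.015, tau_c = 0.005, snr_db = 20, seed = 5)
  # remove DC/Nyquist so the one-sided spectral sum is exact
  g <- win$grid_segment
  flat <- matrix(aperm(g, c(3, 1, 2)), nrow = dim(g)[3])
  flat <- bandpass_fft(flat, win$fs_hz, 0.3, 20)
  win$grid_segment <- aperm(array(flat, dim = dim(g)[c(3, 1, 2)]), c(2, 3, 1))
  w <- estimate_channel_weights(win)
  # integer-sample delays so the time-domain shift is an exact circular shift
  k_r <- 3; k_c <- -2
  dl <- list(tau_r_s = k_r / win$fs_hz, tau_c_s = k_c / win$fs_hz)
  sh <- estimate_reference_shape(win, dl, w)
  shape_t <- Re(fft(sh$spectrum, inverse = TRUE)) / sh$n_samples
  td <- timedomain_cost(win, shape_t, k_r, k_c, w)
  fd <- cost_e2(dl, win, sh, w)
  expect_lt(abs(fd - td) / td, 1e-6)
})

test_that("the cost is invariant under a common time shift", {
  win <- make_plane_window(tau_r = 0.011, tau_c = 0.009, snr_db = 15, seed = 2)
  dl <- list(tau_r_s = 0.011, tau_c_s = 0.009)
  sh <- estimate_reference_shape(win, dl)
  base <- cost_e2(dl, win, sh)
  k <- 17
  g <- win$grid_segment
  n <- dim(g)[3]
  idx <- ((seq_len(n) - 1 - k) %% n) + 1
  win2 <- win
  win2$grid_segment <- g[, , idx, drop = FALSE]
  f <- c(0:(n / 2), -(n / 2 - 1):-1) * win$fs_hz / n
  sh2 <- sh
  sh2$spectrum <- sh$spectrum * exp(-2i * pi * f * k / win$fs_hz)
  expect_equal(cost_e2(dl, win2, sh2), base, tolerance = 1e-9)
})

test_that("mismatched shape and window lengths are rejected", {
  win <- make_plane_window()
  sh <- estimate_reference_shape(win, list(tau_r_s = 0, tau_c_s = 0))
  sh$n_samples <- sh$n_samples - 1
  expect_error(cost_e2(list(tau_r_s = 0, tau_c_s = 0), win, sh),
               class = "ehgcv_invalid_argument")
})

test_that("delays of a noiseless simulated window are recovered to 1e-4 s", {
  sc <- sim_scenario(duration_s = 30, contraction_schedule = rbind(c(5, 20)),
                     true_cv_cm_s = 10, true_angle_rad = pi / 4,
                     snr_db = Inf, spike_jitter_frac = 0, rng_seed = 1)
  rec <- generate_grid_recording(sc)
  win <- segment_contraction(list(onset_s = 5, duration_s = 20), rec)[[1]]
  dp <- estimate_delays(win)
  truth <- cv_to_delays(10, pi / 4, 0.5)    # tau_r = tau_c ~ 0.03536 s
  expect_true(dp$converged)
  expect_lt(abs(dp$tau_r_s - truth$tau_r_s), 1e-4)
  expect_lt(abs(dp$tau_c_s - truth$tau_c_s), 1e-4)
})

test_that("degenerate windows are refused", {
  set.seed(4)
  g <- array(rnorm(2 * 2 * 400), dim = c(2, 2, 400))
  g[1, , ] <- 0
  g[2, 2, ] <- 0                            # only one live row left
  expect_error(estimate_delays(analysis_window(g, 200, 0.5)),
               class = "ehgcv_degenerate_input")
})

test_that("delay pairs convert to CV vectors per the plane-wave geometry", {
  v1 <- delays_to_cv(list(tau_r_s = 0.05, tau_c_s = 0), 0.5)
  expect_equal(v1$amplitude_cm_s, 10)
  expect_equal(v1$angle_rad, 0)
  v2 <- delays_to_cv(list(tau_r_s = 0, tau_c_s = -0.05), 0.5)
  expect_equal(v2$amplitude_cm_s, 10)
  expect_equal(v2$angle_rad, -pi / 2)
  v3 <- delays_to_cv(list(tau_r_s = 0, tau_c_s = 0), 0.5)
  expect_true(v3$excluded)
  expect_equal(v3$reason, "zero-delay")
})

test_that("the outlier rule excludes strictly above 30 cm/s", {
  cvs <- do.call(rbind, lapply(c(8, 35, 12, 30), function(a)
    delays_to_cv(cv_to_delays(a, 0.4, 0.5), 0.5)))
  out <- filter_outliers(cvs)
  expect_equal(out$excluded, c(FALSE, TRUE, FALSE, FALSE)) # 30.0 retained
  expect_equal(out$reason[2], "supra-physiological")
  expect_equal(nrow(filter_outliers(cvs[0, ])), 0)
})
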