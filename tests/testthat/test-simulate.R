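noiseless_scenario <- function(cv, angle, seed = 1, jitter = 0) {
  sim_scenario(duration_s = 40, contraction_schedule = rbind(c(10, 20)),
               true_cv_cm_s = cv, true_angle_rad = angle, snr_db = Inf,
               spike_jitter_frac = jitter, rng_seed = seed)
}

test_that("vertical propagation delays rows and leaves columns identical", {
  rec <- generate_grid_recording(noiseless_scenario(10, 0))
  # tau_r = d/CV = 0.05 s = 10 samples; tau_c = 0
  for (cc in c(1, 4, 8)) {
    x1 <- rec$grid[1, cc, ]
    x2 <- rec$grid[2, cc, ]
    expect_lt(max(abs(x2[-(1:10)] - x1[seq_len(length(x1) - 10)])), 1e-8)
  }
  expect_equal(rec$grid[3, 1, ], rec$grid[3, 7, ], tolerance = 1e-12)
})

test_that("horizontal propagation leaves rows identical and delays columns", {
  rec <- generate_grid_recording(noiseless_scenario(10, pi / 2))
  expect_equal(rec$grid[1, 3, ], rec$grid[6, 3, ], tolerance = 1e-12)
  x1 <- rec$grid[2, 1, ]
  x2 <- rec$grid[2, 2, ]
  expect_lt(max(abs(x2[-(1:10)] - x1[seq_len(length(x1) - 10)])), 1e-8)
})

test_that("corner-to-corner cross-correlation lag matches the scheduled delays", {
  cv <- 8; angle <- pi / 5
  rec <- generate_grid_recording(noiseless_scenario(cv, angle, seed = 4))
  tau <- cv_to_delays(cv, angle, rec$electrode_spacing_cm)
  expected <- round(7 * (tau$tau_r_s + tau$tau_c_s) * rec$fs_hz)
  lag <- xcorr_lag(rec$grid[1, 1, ], rec$grid[8, 8, ], max_lag = 400)
  expect_equal(lag, expected)
})

test_that("sub-sample delays survive upsampled cross-correlation", {
  # delay between adjacent rows recovered to within 1/(2 fs upsample)
  up <- 8
  for (cv in c(7.3, 13.1)) {
    rec <- generate_grid_recording(noiseless_scenario(cv, 0.3, seed = 2))
    tau <- cv_to_delays(cv, 0.3, rec$electrode_spacing_cm)
    x1 <- upsample_fft(rec$grid[1, 1, ], up)
    x2 <- upsample_fft(rec$grid[2, 1, ], up)
    lag <- xcorr_lag(x1, x2, max_lag = 40 * up)
    expect_lt(abs(lag / (rec$fs_hz * up) - tau$tau_r_s),
              1 / (2 * rec$fs_hz * up) + 1e-12)
  }
})

test_that("identical seeds reproduce recordings bit for bit", {
  sc <- sim_scenario(duration_s = 60, contraction_schedule = rbind(c(10, 30)),
                     snr_db = 10, rng_seed = 11)
  r1 <- generate_grid_recording(sc)
  r2 <- generate_grid_recording(sc)
  expect_identical(r1$grid, r2$grid)
  expect_identical(r1$bipolar, r2$bipolar)
  sc2 <- sim_scenario(duration_s = 60, contraction_schedule = rbind(c(10, 30)),
                      snr_db = 10, rng_seed = 12)
  expect_false(identical(generate_grid_recording(sc2)$grid, r1$grid))
})

test_that("empirical SNR matches the requested level within 0.5 dB", {
  for (snr in c(5, 10, 20)) {
    sc_n <- sim_scenario(duration_s = 60, contraction_schedule = rbind(c(10, 40)),
                         snr_db = snr, rng_seed = 21)
    sc_c <- sim_scenario(duration_s = 60, contraction_schedule = rbind(c(10, 40)),
                         snr_db = Inf, rng_seed = 21)
    noisy <- generate_grid_recording(sc_n)
    clean <- generate_grid_recording(sc_c)
    emp <- 10 * log10(mean(clean$grid^2) / mean((noisy$grid - clean$grid)^2))
    expect_lt(abs(emp - snr), 0.5)
  }
})

test_that("simulator annotations follow the schedule", {
  sc <- sim_scenario(duration_s = 300,
                     contraction_schedule = rbind(c(30, 40), c(150, 50)),
                     rng_seed = 5)
  rec <- generate_grid_recording(sc)
  expect_equal(rec$toco_marks, sc$contraction_schedule)
  expect_equal(rec$perception_marks, c(50, 175))
})

test_that("impossible geometry and schedules are rejected", {
  # delay span (7 * 0.5/1 = 3.5 s per axis) cannot fit a 4 s contraction
  sc <- sim_scenario(duration_s = 40, contraction_schedule = rbind(c(10, 4)),
                     true_cv_cm_s = 1, true_angle_rad = pi / 4, rng_seed = 1)
  expect_error(generate_grid_recording(sc), class = "ehgcv_invalid_argument")
  expect_error(sim_scenario(duration_s = 100,
                            contraction_schedule = rbind(c(10, 30), c(20, 30))),
               class = "ehgcv_invalid_argument") # overlap
  expect_error(sim_scenario(duration_s = 50,
                            contraction_schedule = rbind(c(40, 30))),
               class = "ehgcv_invalid_argument") # beyond the end
  expect_error(sim_scenario(duration_s = 50, n_rows = 1,
                            contraction_schedule = rbind(c(10, 20))),
               class = "ehgcv_invalid_argument")
})
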