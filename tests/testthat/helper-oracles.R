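# Independent oracles and small constructors shared across tests. Everything
# here recomputes quantities through routes that do not touch the package's
# estimation code paths.

# Direct DFT power-spectral centroid (plain double loop over the definition).
dft_centroid <- function(x, fs) {
  n <- length(x)
  nb <- n %/% 2
  p <- numeric(nb)
  for (k in seq_len(nb)) {
    ph <- exp(-2i * pi * (k - 1) * (0:(n - 1)) / n)
    p[k] <- Mod(sum(x * ph))^2
  }
  f <- (seq_len(nb) - 1) * fs / n
  sum(f * p) / sum(p)
}

# Integer-lag cross-correlation argmax by direct summation.
xcorr_lag <- function(x, y, max_lag) {
  lags <- -max_lag:max_lag
  n <- length(x)
  vals <- vapply(lags, function(l) {
    if (l >= 0) sum(x[seq_len(n - l)] * y[seq_len(n - l) + l])
    else sum(x[seq_len(n + l) - l] * y[seq_len(n + l)])
  }, 0)
  lags[which.max(vals)]
}

# FFT zero-padding upsampler (band-limited interpolation) for sub-sample
# cross-correlation checks.
upsample_fft <- function(x, factor) {
  n <- length(x)
  X <- stats::fft(x)
  m <- n * factor
  Y <- complex(m)
  half <- n %/% 2
  Y[1:(half + 1)] <- X[1:(half + 1)]
  Y[(m - half + 2):m] <- X[(n - half + 2):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# Plane-wave analysis window built from a closed-form Gaussian-derivative
# pulse evaluated directly (no package code): channel (r, c) sees the pulse
# at t0 + (r-1) tau_r + (c-1) tau_c.
make_plane_window <- function(nr = 4, nc = 4, fs = 200, dur = 2,
                              tau_r = 0.012, tau_c = 0.007,
                              t0 = dur / 2, width = 0.1, amp = 50,
                              snr_db = Inf, seed = 1) {
  n <- round(dur * fs)
  t <- (0:(n - 1)) / fs
  sigma <- width / 8
  g <- array(0, dim = c(nr, nc, n))
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    u <- (t - t0 - (r - 1) * tau_r - (cc - 1) * tau_c) / sigma
    g[r, cc, ] <- -amp * u * exp(-u^2 / 2) * exp(0.5)
  }
  if (is.finite(snr_db)) {
    set.seed(seed)
    sd_n <- sqrt(mean(g^2) / 10^(snr_db / 10))
    g <- g + array(rnorm(length(g), sd = sd_n), dim = dim(g))
  }
  analysis_window(g, fs, 0.5)
}

# Exhaustive delay-lattice search: enumerates every (tau_r, tau_c) pair on a
# regular grid and picks the one maximizing the coherent steered power (by
# Parseval, equivalently minimizing the time-domain weighted SSD about the
# realigned mean). Pure enumeration, no iterative refinement.
brute_force_delays <- function(win, step = 1e-4, tau_max = 0.09,
                               f_band = c(0.3, 5), weights = NULL) {
  g <- win$grid_segment
  d <- dim(g)
  n <- d[3]
  fs <- win$fs_hz
  w <- if (is.null(weights)) matrix(1, d[1], d[2]) else unclass(weights)
  flat <- matrix(aperm(g, c(3, 1, 2)), nrow = n)
  X <- stats::mvfft(flat)
  f_all <- (0:(n - 1)) * fs / n
  keep <- which(f_all >= f_band[1] & f_all <= f_band[2])
  Xb <- X[keep, , drop = FALSE]
  f <- f_all[keep]
  taus <- seq(-tau_max, tau_max, by = step)
  nt <- length(taus)
  pow <- matrix(0, nt, nt)     # [tau_r, tau_c]
  for (k in seq_along(f)) {
    Pf <- exp(2i * pi * f[k] * outer(0:(d[1] - 1), taus))   # nr x nt
    Cf <- exp(2i * pi * f[k] * outer(0:(d[2] - 1), taus))   # nc x nt
    Xk <- w * matrix(Xb[k, ], nrow = d[1])                   # nr x nc, weighted
    pow <- pow + Mod(t(Pf) %*% Xk %*% Cf)^2
  }
  best <- arrayInd(which.max(pow), dim(pow))
  list(tau_r_s = taus[best[1]], tau_c_s = taus[best[2]])
}

# Time-domain weighted SSD between channels and an integer-sample circularly
# shifted reference shape (exact, no interpolation).
timedomain_cost <- function(win, shape_t, shift_r, shift_c, weights = NULL) {
  g <- win$grid_segment
  d <- dim(g)
  n <- d[3]
  w <- if (is.null(weights)) matrix(1, d[1], d[2]) else unclass(weights)
  total <- 0
  for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    k <- (r - 1) * shift_r + (cc - 1) * shift_c
    shifted <- shape_t[((seq_len(n) - 1 - k) %% n) + 1]
    total <- total + w[r, cc] * sum((g[r, cc, ] - shifted)^2)
  }
  total
}

# Minimal iup_estimate for feeding synthetic Psi traces to the detector.
make_iup <- function(psi, hop_s = 5, t0 = 10) {
  structure(list(psi = psi,
                 frame_times_s = t0 + hop_s * (seq_along(psi) - 1),
                 frame_hop_s = hop_s, f_min_hz = 0.3, f_max_hz = 0.8),
            class = "iup_estimate")
}

wrap_angle <- function(a) atan2(sin(a), cos(a))
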