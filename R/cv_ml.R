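#' Configuration for the maximum-likelihood delay search
#'
#' @param cv_min_cm_s slowest admissible propagation; sets the coarse search
#'   range `tau_max = d / cv_min` (default 1 cm/s — slower is treated as
#'   non-propagating).
#' @param cv_max_cm_s outlier threshold passed through to downstream filtering
#'   (default 30 cm/s).
#' @param coarse_step_s coarse grid step in seconds (default 0.02 s; the
#'   band-limited pulse autocorrelation main lobe is ~0.2 s wide, so the basin
#'   of the global optimum cannot be missed).
#' @param f_band_hz frequency band (Hz) over which spectral sums run; signals
#'   are expected to be pre-filtered to this band (out-of-band bins are zero).
#' @param tol_s convergence tolerance on the delay update (default 1e-5 s).
#' @param max_iter maximum outer iterations (default 20).
#' @param tau_max_s optional explicit search half-range, overriding
#'   `d / cv_min_cm_s`.
#' @export
cv_search_config <- function(cv_min_cm_s = 1, cv_max_cm_s = 30,
                             coarse_step_s = 0.02, f_band_hz = c(0.3, 5),
                             tol_s = 1e-5, max_iter = 20, tau_max_s = NULL) {
  if (cv_min_cm_s <= 0 || cv_max_cm_s <= cv_min_cm_s)
    stop_invalid("need 0 < cv_min_cm_s < cv_max_cm_s")
  if (coarse_step_s <= 0 || tol_s <= 0 || max_iter < 1)
    stop_invalid("coarse_step_s, tol_s must be positive; max_iter >= 1")
  structure(list(cv_min_cm_s = cv_min_cm_s, cv_max_cm_s = cv_max_cm_s,
                 coarse_step_s = coarse_step_s, f_band_hz = f_band_hz,
                 tol_s = tol_s, max_iter = as.integer(max_iter),
                 tau_max_s = tau_max_s),
            class = "cv_search_config")
}

# Internal spectral workspace: band-limited FFTs of all channels plus the
# quantities every cost evaluation reuses.
.spectral_ws <- function(window, f_band_hz) {
  g <- window$grid_segment
  d <- dim(g)
  n <- d[3]
  fs <- window$fs_hz
  flat <- matrix(aperm(g, c(3, 1, 2)), nrow = n)   # samples x (r fastest)
  X <- stats::mvfft(flat)
  f_all <- (0:(n - 1)) * fs / n
  keep <- which(f_all >= f_band_hz[1] & f_all <= min(f_band_hz[2], fs / 2))
  list(Xb = X[keep, , drop = FALSE], f = f_all[keep], n = n,
       nr = d[1], nc = d[2], fs = fs,
       rows = rep(seq_len(d[1]), times = d[2]),
       cols = rep(seq_len(d[2]), each = d[1]))
}

# Steered, weighted coherent power at candidate delays; the optimal-shape
# residual cost is (2/n) * (sum_ch w |X|^2 - power / sum w), so maximizing
# this power minimizes E^2 with the least-squares-optimal reference shape
# embedded.
.steered_power <- function(ws, w_vec, tau_r, tau_c) {
  ph <- exp(2i * pi * ws$f %o% ((ws$rows - 1) * tau_r + (ws$cols - 1) * tau_c))
  A <- (ws$Xb * ph) %*% w_vec
  sum(Mod(A)^2)
}

# Separable exhaustive scan over a delay lattice: returns the power matrix
# (length(taus_r) x length(taus_c)).
.scan_power <- function(ws, w_vec, taus_r, taus_c) {
  nf <- length(ws$f)
  ntc <- length(taus_c)
  # B[f, tau_c, r] = sum_c w X e^{+j 2 pi f (c-1) tau_c}
  B <- array(0i, dim = c(nf, ntc, ws$nr))
  for (ch in seq_along(w_vec)) {
    if (w_vec[ch] == 0) next
    r <- ws$rows[ch]; cc <- ws$cols[ch]
    ph_c <- exp(2i * pi * ws$f %o% ((cc - 1) * taus_c))
    B[, , r] <- B[, , r] + (w_vec[ch] * ws$Xb[, ch]) * ph_c
  }
  pow <- matrix(0, nrow = length(taus_r), ncol = ntc)
  for (i in seq_along(taus_r)) {
    A <- matrix(0i, nrow = nf, ncol = ntc)
    for (r in seq_len(ws$nr))
      A <- A + exp(2i * pi * ws$f * (r - 1) * taus_r[i]) * B[, , r]
    pow[i, ] <- colSums(Mod(A)^2)
  }
  pow
}

#' Least-squares reference shape given delays
#'
#' Realigns every channel's spectrum to the (1, 1) origin by the phase
#' `exp(+j 2 pi f [(r-1) tau_r + (c-1) tau_c])` and forms the weighted mean —
#' the shape minimizing the residual cost at those delays.
#'
#' @param window an [analysis_window()].
#' @param delays a `delay_pair` or list with `tau_r_s`, `tau_c_s`.
#' @param weights optional [estimate_channel_weights()] matrix (uniform if
#'   `NULL`).
#' @return object of class `reference_shape`: `spectrum` (full-length complex
#'   DFT, Hermitian so the time shape is real), `n_samples`, `fs_hz`.
#' @export
estimate_reference_shape <- function(window, delays, weights = NULL) {
  g <- window$grid_segment
  d <- dim(g)
  n <- d[3]
  if (!all(is.finite(c(delays$tau_r_s, delays$tau_c_s))))
    stop_invalid("delays must be finite")
  w <- if (is.null(weights)) matrix(1, d[1], d[2]) else unclass(weights)
  flat <- matrix(aperm(g, c(3, 1, 2)), nrow = n)
  X <- stats::mvfft(flat)
  f <- signed_freqs(n, window$fs_hz)   # signed so the shape stays Hermitian
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  w_vec <- as.numeric(w)[rows + (cols - 1) * d[1]]
  ph <- exp(2i * pi * f %o% ((rows - 1) * delays$tau_r_s + (cols - 1) * delays$tau_c_s))
  S <- (X * ph) %*% w_vec / sum(w_vec)
  structure(list(spectrum = as.vector(S), n_samples = n, fs_hz = window$fs_hz),
            class = "reference_shape")
}

#' Weighted spectral residual cost E-squared
#'
#' `E^2 = (2/N) sum_ch w_ch sum_{f=0}^{N/2-1} |X_ch(f) - S(f) e^{-j 2 pi f
#' [(r-1) tau_r + (c-1) tau_c]}|^2`. Under white Gaussian channel noise its
#' minimizer over the delays is the maximum-likelihood estimate; by Parseval
#' it equals the time-domain weighted sum of squared differences between each
#' channel and the fractionally shifted reference shape (for signals without
#' DC/Nyquist content). Zero, to numerical precision, at the generating
#' delays of a noiseless plane-wave recording.
#'
#' @param delays list with `tau_r_s`, `tau_c_s` (seconds).
#' @param window an [analysis_window()].
#' @param shape an [estimate_reference_shape()] result of matching length.
#' @param weights optional channel-weight matrix (uniform if `NULL`).
#' @return nonnegative scalar.
#' @export
cost_e2 <- function(delays, window, shape, weights = NULL) {
  g <- window$grid_segment
  d <- dim(g)
  n <- d[3]
  if (shape$n_samples != n)
    stop_invalid("shape length (%d) != window length (%d)", shape$n_samples, n)
  w <- if (is.null(weights)) matrix(1, d[1], d[2]) else unclass(weights)
  flat <- matrix(aperm(g, c(3, 1, 2)), nrow = n)
  X <- stats::mvfft(flat)
  keep <- seq_len(max(1L, floor(n / 2)))        # f = 0 .. N/2 - 1
  f <- (keep - 1) * window$fs_hz / n
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  w_vec <- as.numeric(w)[rows + (cols - 1) * d[1]]
  ph <- exp(-2i * pi * f %o% ((rows - 1) * delays$tau_r_s + (cols - 1) * delays$tau_c_s))
  R <- X[keep, , drop = FALSE] - shape$spectrum[keep] * ph
  as.numeric(2 / n * sum(t(Mod(R)^2) * w_vec))
}

#' Maximum-likelihood estimation of the plane-wave delays
#'
#' Estimates the inter-row and inter-column delays `(tau_r, tau_c)` of the
#' plane-wave model by minimizing the weighted spectral residual [cost_e2()]
#' with the least-squares-optimal reference shape embedded (so minimizing the
#' cost is maximizing the steered coherent power). The search runs in the
#' frequency domain, where the delays are continuous — no sampling-resolution
#' limit: (i) exhaustive coarse scan over a `[-tau_max, tau_max]^2` lattice,
#' (ii) local lattice refinement, (iii) Nelder-Mead continuous minimization,
#' then the channel weights are re-estimated from the residuals about the
#' realigned shape and the minimization repeated until the delay update falls
#' below `tol_s`.
#'
#' @param window an [analysis_window()]; channels should be band-limited to
#'   `search_cfg$f_band_hz` (as produced by [segment_contraction()]).
#' @param weights optional [estimate_channel_weights()] matrix; estimated from
#'   the window when `NULL`, and iteratively refined from residual variances.
#' @param search_cfg a [cv_search_config()].
#' @return object of class `delay_pair`: `tau_r_s`, `tau_c_s`, `cost` (E^2 at
#'   the optimum), `converged`, `n_iter`, plus the final `weights`.
#' @export
estimate_delays <- function(window, weights = NULL,
                            search_cfg = cv_search_config()) {
  cfg <- search_cfg
  g <- window$grid_segment
  d <- dim(g)
  if (d[3] < window$fs_hz) stop_invalid("window must span at least 1 s")
  refine_weights <- is.null(weights)
  w <- if (is.null(weights)) estimate_channel_weights(window) else weights
  wm <- unclass(w)
  if (sum(rowSums(wm > 0) > 0) < 2 || sum(colSums(wm > 0) > 0) < 2)
    stop_degenerate("need live channels in at least 2 rows and 2 columns")

  ws <- .spectral_ws(window, cfg$f_band_hz)
  if (length(ws$f) < 2) stop_invalid("fewer than 2 spectral bins in the band")
  w_vec <- as.numeric(wm)[ws$rows + (ws$cols - 1) * ws$nr]
  tau_max <- cfg$tau_max_s %||% (window$electrode_spacing_cm / cfg$cv_min_cm_s)

  # (i) coarse lattice
  taus <- seq(-tau_max, tau_max, by = cfg$coarse_step_s)
  pow <- .scan_power(ws, w_vec, taus, taus)
  best <- arrayInd(which.max(pow), dim(pow))
  est <- c(taus[best[1]], taus[best[2]])
  # (ii) local lattice refinement
  fine_step <- cfg$coarse_step_s / 5
  fr <- seq(est[1] - cfg$coarse_step_s, est[1] + cfg$coarse_step_s, by = fine_step)
  fc <- seq(est[2] - cfg$coarse_step_s, est[2] + cfg$coarse_step_s, by = fine_step)
  pow <- .scan_power(ws, w_vec, fr, fc)
  best <- arrayInd(which.max(pow), dim(pow))
  est <- c(fr[best[1]], fc[best[2]])

  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # (iii) continuous minimization of the embedded-shape cost
    opt <- stats::optim(est, function(p) -.steered_power(ws, w_vec, p[1], p[2]),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    delta <- max(abs(opt$par - est))
    est <- opt$par
    if (refine_weights) {
      dp <- list(tau_r_s = est[1], tau_c_s = est[2])
      sh <- estimate_reference_shape(window, dp, w)
      w_new <- .residual_weights(window, dp, sh, wm)
      w_vec_new <- as.numeric(w_new)[ws$rows + (ws$cols - 1) * ws$nr]
      wchange <- max(abs(w_vec_new - w_vec))
      wm <- w_new
      w <- structure(wm, class = "channel_weights")
      w_vec <- w_vec_new
    } else wchange <- 0
    if ((delta < cfg$tol_s && wchange < 1e-3) || iter >= cfg$max_iter) {
      converged <- delta < cfg$tol_s
      break
    }
  }

  dp <- list(tau_r_s = est[1], tau_c_s = est[2])
  sh <- estimate_reference_shape(window, dp, w)
  structure(list(tau_r_s = est[1], tau_c_s = est[2],
                 cost = cost_e2(dp, window, sh, w),
                 converged = converged, n_iter = iter, weights = w),
            class = "delay_pair")
}

# Channel weights from residual variance about the realigned reference shape.
.residual_weights <- function(window, delays, shape, w_prev) {
  g <- window$grid_segment
  d <- dim(g)
  n <- d[3]
  flat <- matrix(aperm(g, c(3, 1, 2)), nrow = n)
  X <- stats::mvfft(flat)
  f <- signed_freqs(n, window$fs_hz)
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  ph <- exp(-2i * pi * f %o% ((rows - 1) * delays$tau_r_s + (cols - 1) * delays$tau_c_s))
  R <- X - shape$spectrum * ph
  rv <- colSums(Mod(R)^2) / n^2                # time-domain residual MS
  dead <- as.numeric(w_prev) == 0
  rv <- pmax(rv, 1e-12 * max(rv, na.rm = TRUE))
  w <- 1 / rv
  w[dead] <- 0
  if (!any(w > 0)) stop_degenerate("all channels dead after reweighting")
  w <- w / mean(w[!dead])
  matrix(w, nrow = d[1], ncol = d[2])
}

#' @export
print.delay_pair <- function(x, ...) {
  cat(sprintf("delay_pair: tau_r = %.6f s, tau_c = %.6f s (E2 = %.4g, %s, %d iter)\n",
              x$tau_r_s, x$tau_c_s, x$cost,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}
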