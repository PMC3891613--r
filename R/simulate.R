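#' Generate a synthetic grid recording
#'
#' Realizes the plane-wave signal model: every channel `(r, c)` of the grid
#' records the same action-potential shape delayed by
#' `(r - 1) tau_r + (c - 1) tau_c` seconds relative to channel (1, 1), plus
#' independent white Gaussian noise at the requested SNR. Fractional delays
#' are exact: the pulse is an analytic waveform evaluated at the delayed
#' sample times, so no interpolation error is introduced. Spike times are
#' confined to the interior of each scheduled contraction with a margin of
#' half a pulse width plus the full grid delay span, so every channel's burst
#' stays inside the scheduled interval (a schedule too short for the delay
#' span is rejected). The bipolar channel is a virtual differential pair
#' displaced along the propagation path by a fixed 0.3 s electrical delay; it
#' carries the burst's in-band (0.3-0.8 Hz) spike-repetition content used for
#' contraction timing. Tocodynamometer marks copy the schedule; maternal
#' perception marks are the contraction midpoints.
#'
#' @param scenario a [sim_scenario()].
#' @return object of class `grid_recording` with elements `grid` (array
#'   `n_rows x n_cols x n_samples`, microvolt), `bipolar` (numeric vector),
#'   `fs_hz`, `electrode_spacing_cm`, `toco_marks` (matrix onset/duration),
#'   `perception_marks` (numeric vector of instants), and `ground_truth`
#'   (the scenario).
#' @export
generate_grid_recording <- function(scenario) {
  if (!inherits(scenario, "sim_scenario"))
    stop_invalid("scenario must be a sim_scenario")
  sc <- scenario
  nt <- round(sc$duration_s * sc$fs_hz)
  tt <- (seq_len(nt) - 1) / sc$fs_hz
  nr <- sc$n_rows; nc <- sc$n_cols
  half_support <- sc$ap_width_s / 2          # pulse truncated at 4 sigma
  bip_offset_s <- 0.3

  with_seed(sc$rng_seed, {
    clean <- array(0, dim = c(nr, nc, nt))
    bip_clean <- numeric(nt)
    nk <- nrow(sc$contraction_schedule)
    for (k in seq_len(nk)) {
      onset <- sc$contraction_schedule[k, 1]
      dur <- sc$contraction_schedule[k, 2]
      tau <- cv_to_delays(sc$true_cv_cm_s[k], sc$true_angle_rad[k],
                          sc$electrode_spacing_cm)
      D <- outer((seq_len(nr) - 1) * tau$tau_r_s,
                 (seq_len(nc) - 1) * tau$tau_c_s, `+`)
      lo <- onset + half_support + max(0, -min(D))
      hi <- onset + dur - half_support - max(0, max(D), bip_offset_s)
      if (hi <= lo)
        stop_invalid(
          "grid delay span (%.3f s) plus pulse width leaves no room in a %.1f s contraction",
          max(D) - min(D), dur)
      # jittered spike train within [lo, hi]
      mean_gap <- 1 / sc$spike_rate_hz
      gaps <- mean_gap * (1 + sc$spike_jitter_frac *
                            stats::runif(ceiling((hi - lo) / mean_gap) + 1, -1, 1))
      spikes <- lo + cumsum(c(0, gaps))
      spikes <- spikes[spikes <= hi]
      for (t0 in spikes) {
        for (r in seq_len(nr)) for (cc in seq_len(nc)) {
          center <- t0 + D[r, cc]
          i0 <- max(1L, floor((center - half_support) * sc$fs_hz) + 1L)
          i1 <- min(nt, ceiling((center + half_support) * sc$fs_hz) + 1L)
          idx <- i0:i1
          clean[r, cc, idx] <- clean[r, cc, idx] +
            sc$ap_amplitude_uv * ap_pulse(tt[idx] - center, sc$ap_width_s, sc$ap_shape)
        }
        # virtual bipolar pair: pulse minus the same pulse 0.3 s later
        for (sgn in c(1, -1)) {
          center <- t0 + if (sgn == 1) 0 else bip_offset_s
          i0 <- max(1L, floor((center - half_support) * sc$fs_hz) + 1L)
          i1 <- min(nt, ceiling((center + half_support) * sc$fs_hz) + 1L)
          idx <- i0:i1
          bip_clean[idx] <- bip_clean[idx] +
            sgn * sc$ap_amplitude_uv * ap_pulse(tt[idx] - center, sc$ap_width_s, sc$ap_shape)
        }
      }
    }

    if (is.finite(sc$snr_db)) {
      p_sig <- mean(clean^2)
      if (p_sig == 0) {
        sigma <- 0
      } else {
        sigma2 <- p_sig / 10^(sc$snr_db / 10)
        if (!is.finite(sigma2)) stop_invalid("snr_db %g produces non-finite noise power", sc$snr_db)
        sigma <- sqrt(sigma2)
      }
      grid <- clean + array(stats::rnorm(length(clean), sd = sigma), dim = dim(clean))
      p_bip <- mean(bip_clean^2)
      sig_b <- if (p_bip > 0) sqrt(p_bip / 10^(sc$snr_db / 10)) else 0
      bip <- bip_clean + stats::rnorm(nt, sd = sig_b)
    } else {
      grid <- clean
      bip <- bip_clean
    }

    perception <- if (nk > 0)
      sc$contraction_schedule[, 1] + sc$contraction_schedule[, 2] / 2 else numeric(0)
    structure(list(
      grid = grid,
      bipolar = bip,
      fs_hz = sc$fs_hz,
      electrode_spacing_cm = sc$electrode_spacing_cm,
      toco_marks = sc$contraction_schedule,
      perception_marks = perception,
      ground_truth = sc
    ), class = "grid_recording")
  })
}

#' Construct a grid recording from raw components
#'
#' Low-level constructor used by the EDF reader and by tests; validates the
#' shared-length and positivity invariants.
#' @param grid numeric array `n_rows x n_cols x n_samples` (microvolt).
#' @param bipolar numeric vector, same number of samples as `grid`.
#' @param fs_hz sampling rate (> 0).
#' @param electrode_spacing_cm interelectrode distance (> 0).
#' @param toco_marks two-column matrix of `(onset_s, duration_s)` intervals.
#' @param perception_marks numeric vector of annotated instants (s).
#' @param ground_truth optional [sim_scenario()].
#' @export
grid_recording <- function(grid, bipolar, fs_hz, electrode_spacing_cm,
                           toco_marks = matrix(numeric(0), ncol = 2),
                           perception_marks = numeric(0),
                           ground_truth = NULL) {
  if (length(dim(grid)) != 3) stop_invalid("grid must be a 3-d array")
  if (length(bipolar) != dim(grid)[3])
    stop_invalid("bipolar channel length (%d) != grid samples (%d)",
                 length(bipolar), dim(grid)[3])
  if (fs_hz <= 0 || electrode_spacing_cm <= 0)
    stop_invalid("fs_hz and electrode_spacing_cm must be positive")
  toco <- matrix(as.numeric(toco_marks), ncol = 2,
                 dimnames = list(NULL, c("onset_s", "duration_s")))
  structure(list(grid = grid, bipolar = bipolar, fs_hz = fs_hz,
                 electrode_spacing_cm = electrode_spacing_cm,
                 toco_marks = toco,
                 perception_marks = as.numeric(perception_marks),
                 ground_truth = ground_truth),
            class = "grid_recording")
}

#' @export
print.grid_recording <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("grid_recording: %d x %d grid + bipolar, %d samples @ %g Hz (%.1f s)\n",
              d[1], d[2], d[3], x$fs_hz, d[3] / x$fs_hz))
  cat(sprintf("  d = %g cm; %d toco mark(s); %d perception mark(s); %s ground truth\n",
              x$electrode_spacing_cm, nrow(x$toco_marks),
              length(x$perception_marks),
              if (is.null(x$ground_truth)) "no" else "with"))
  invisible(x)
}
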