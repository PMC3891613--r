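#' Construct an analysis window
#'
#' @param grid_segment numeric array `n_rows x n_cols x n_samples`.
#' @param fs_hz sampling rate in Hz.
#' @param electrode_spacing_cm interelectrode distance in cm.
#' @param start_s absolute start time of the window in the recording.
#' @param parent_contraction identifier of the parent contraction.
#' @export
analysis_window <- function(grid_segment, fs_hz, electrode_spacing_cm,
                            start_s = 0, parent_contraction = NA_integer_) {
  if (length(dim(grid_segment)) != 3) stop_invalid("grid_segment must be a 3-d array")
  if (dim(grid_segment)[3] < 2) stop_invalid("window must contain at least 2 samples")
  if (fs_hz <= 0 || electrode_spacing_cm <= 0)
    stop_invalid("fs_hz and electrode_spacing_cm must be positive")
  structure(list(grid_segment = grid_segment, fs_hz = fs_hz,
                 electrode_spacing_cm = electrode_spacing_cm,
                 start_s = start_s, parent_contraction = parent_contraction),
            class = "analysis_window")
}

#' Split a contraction into overlapping analysis windows
#'
#' Windows advance by `window_length_s - overlap_s`; a trailing window that
#' would exceed the contraction is dropped (no partial windows). Each window's
#' grid data are extracted from the recording and, by default, band-pass
#' filtered 0.3-5 Hz zero-phase (identically on every channel, so delays are
#' untouched) to remove drift and out-of-band noise before delay estimation.
#'
#' @param contraction one row of a [detect_contractions()] result, or any list
#'   with `onset_s` and `duration_s`.
#' @param recording a [grid_recording()].
#' @param window_length_s window length in seconds (default 10 s).
#' @param overlap_s overlap between consecutive windows (default 5 s).
#' @param f_band_hz length-2 band for the zero-phase pre-filter, or `NULL` to
#'   skip filtering.
#' @param contraction_id identifier stored in each window.
#' @return list of [analysis_window()] objects (empty when the contraction is
#'   shorter than one window).
#' @export
segment_contraction <- function(contraction, recording,
                                window_length_s = 10, overlap_s = 5,
                                f_band_hz = c(0.3, 5),
                                contraction_id = NA_integer_) {
  if (window_length_s <= overlap_s)
    stop_invalid("window_length_s (%g) must exceed overlap_s (%g)",
                 window_length_s, overlap_s)
  onset <- contraction$onset_s[1]
  dur <- contraction$duration_s[1]
  step <- window_length_s - overlap_s
  if (dur < window_length_s) return(list())
  starts <- onset + seq(0, dur - window_length_s, by = step)
  fs <- recording$fs_hz
  nt <- dim(recording$grid)[3]
  win_n <- round(window_length_s * fs)
  lapply(starts, function(s0) {
    i0 <- floor(s0 * fs) + 1L
    i1 <- min(nt, i0 + win_n - 1L)
    seg <- recording$grid[, , i0:i1, drop = FALSE]
    if (!is.null(f_band_hz)) {
      d <- dim(seg)
      flat <- matrix(aperm(seg, c(3, 1, 2)), nrow = d[3])
      flat <- bandpass_fft(flat, fs, f_band_hz[1], f_band_hz[2])
      seg <- aperm(array(flat, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
    }
    analysis_window(seg, fs, recording$electrode_spacing_cm,
                    start_s = s0, parent_contraction = contraction_id)
  })
}

#' Noise-based channel weights
#'
#' Estimates per-channel noise variance from the power above `hf_lo_hz`
#' (white noise is flat, so the high-frequency band — which the band-limited
#' EHG pulses do not reach — measures the noise floor; the estimate is scaled
#' to the full bandwidth). Weights are inversely proportional to the noise
#' variance, normalized to mean 1 over live channels; channels with (near)
#' zero variance are flagged dead and weighted 0.
#'
#' @param window an [analysis_window()] (pass the unfiltered grid when the
#'   high-frequency noise floor is to be measured).
#' @param hf_lo_hz lower edge of the noise-estimation band; defaults to 10 Hz
#'   or 60% of Nyquist, whichever is smaller.
#' @return object of class `channel_weights`: matrix `n_rows x n_cols`,
#'   finite, >= 0, at least one positive.
#' @export
estimate_channel_weights <- function(window, hf_lo_hz = NULL) {
  g <- window$grid_segment
  d <- dim(g)
  if (d[1] * d[2] < 2) stop_invalid("need at least 2 channels")
  fs <- window$fs_hz
  hf_lo <- hf_lo_hz %||% min(10, 0.6 * fs / 2)
  n <- d[3]
  flat <- matrix(aperm(g, c(3, 1, 2)), nrow = n)     # samples x channels
  tot_var <- apply(flat, 2, stats::var)
  dead <- tot_var <= 1e-12 * max(tot_var)
  if (all(dead)) stop_degenerate("all channels are dead (zero variance)")
  X <- stats::mvfft(flat)
  f <- abs(signed_freqs(n, fs))
  hf <- f >= hf_lo & f <= fs / 2
  if (!any(hf)) hf <- f >= stats::quantile(f, 0.6)
  # mean |X|^2 over HF bins / n estimates the white-noise variance
  nv <- colMeans(Mod(X[hf, , drop = FALSE])^2) / n
  # noiseless channels have an empty HF floor; floor the estimate so they get
  # equal (maximal) weight instead of Inf
  nv <- pmax(nv, 1e-12 * mean(tot_var[!dead]))
  w <- 1 / nv
  w[dead] <- 0
  w <- w / mean(w[!dead])
  structure(matrix(w, nrow = d[1], ncol = d[2]), class = "channel_weights")
}
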