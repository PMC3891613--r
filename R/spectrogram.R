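#' Short-time power spectrogram
#'
#' Hann-windowed short-time Fourier power estimates of a single channel,
#' zero-padded so the frequency bin spacing is at most `freq_res_hz`. Power is
#' normalized so that the sum of the one-sided spectrum of a frame equals the
#' mean power of the frame (Parseval), which makes the spectral moment of
#' [estimate_iup()] carry Hz-times-power units independent of the padding.
#'
#' @param signal numeric vector (the bipolar EHG, microvolt).
#' @param fs_hz sampling rate in Hz.
#' @param window_s analysis window length in seconds (default 20 s).
#' @param hop_s frame hop in seconds (default 5 s).
#' @param freq_res_hz maximum bin spacing in Hz (default 0.025 Hz, at least
#'   20 bins across the 0.3-0.8 Hz band).
#' @return object of class `spectrogram`: `power` (frames x bins, >= 0),
#'   `frame_times_s` (window centers), `freqs_hz`, `frame_hop_s`.
#' @export
compute_spectrogram <- function(signal, fs_hz, window_s = 20, hop_s = 5,
                                freq_res_hz = 0.025) {
  if (fs_hz <= 0) stop_invalid("fs_hz must be positive")
  win_n <- round(window_s * fs_hz)
  hop_n <- max(1L, round(hop_s * fs_hz))
  if (win_n < 16) stop_invalid("window must span at least 16 samples (got %d)", win_n)
  if (hop_n > win_n) stop_invalid("hop_s must not exceed window_s")
  if (length(signal) < win_n)
    stop_invalid("signal (%d samples) shorter than one window (%d)",
                 length(signal), win_n)
  nfft <- 2^ceiling(log2(max(win_n, fs_hz / freq_res_hz)))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win_n) - 1) / (win_n - 1)) # Hann
  wnorm <- sum(w^2)
  starts <- seq(1L, length(signal) - win_n + 1L, by = hop_n)
  nbin <- nfft %/% 2 + 1L
  pow <- matrix(0, nrow = length(starts), ncol = nbin)
  for (i in seq_along(starts)) {
    fr <- signal[starts[i] + 0:(win_n - 1L)] * w
    X <- stats::fft(c(fr, numeric(nfft - win_n)))[seq_len(nbin)]
    p <- Mod(X)^2 / (nfft * wnorm)
    p[c(-1, -nbin)] <- 2 * p[c(-1, -nbin)] # one-sided doubling, not DC/Nyquist
    pow[i, ] <- p
  }
  structure(list(
    power = pow,
    frame_times_s = (starts - 1) / fs_hz + window_s / 2,
    freqs_hz = (seq_len(nbin) - 1) * fs_hz / nfft,
    frame_hop_s = hop_n / fs_hz
  ), class = "spectrogram")
}

#' Estimated intrauterine pressure from the spectrogram
#'
#' The unnormalized first statistical moment of the bipolar EHG spectrogram in
#' a frequency band: `Psi(n) = sum_{f in [f_min, f_max]} f * rho(n, f)`,
#' with inclusive band edges (default 0.3-0.8 Hz). Psi tracks the intensity of
#' uterine electrical bursts and serves only to time contractions; no pressure
#' calibration is applied.
#'
#' @param spec a [compute_spectrogram()] result.
#' @param f_min_hz,f_max_hz band edges in Hz.
#' @return object of class `iup_estimate`: `psi` (one value per frame, >= 0),
#'   `frame_times_s`, `frame_hop_s`, `f_min_hz`, `f_max_hz`.
#' @export
estimate_iup <- function(spec, f_min_hz = 0.3, f_max_hz = 0.8) {
  if (!inherits(spec, "spectrogram")) stop_invalid("spec must be a spectrogram")
  if (f_min_hz >= f_max_hz) stop_invalid("need f_min_hz < f_max_hz")
  idx <- which(spec$freqs_hz >= f_min_hz & spec$freqs_hz <= f_max_hz)
  if (length(idx) == 0 || f_max_hz > max(spec$freqs_hz))
    stop_invalid("band [%g, %g] Hz not covered by the spectrogram", f_min_hz, f_max_hz)
  psi <- as.numeric(spec$power[, idx, drop = FALSE] %*% spec$freqs_hz[idx])
  structure(list(psi = psi,
                 frame_times_s = spec$frame_times_s,
                 frame_hop_s = spec$frame_hop_s,
                 f_min_hz = f_min_hz, f_max_hz = f_max_hz),
            class = "iup_estimate")
}
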