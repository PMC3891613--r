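`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("ehgcv_invalid_argument", "error", "condition")))
}

stop_degenerate <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("ehgcv_degenerate_input", "error", "condition")))
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' simulation helpers are deterministic without clobbering the session stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Signed DFT bin frequencies in Hz for an n-point transform at rate fs.
signed_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

#' Fractional delay by frequency-domain phase shift
#'
#' Applies a (possibly non-integer) delay of `delay_s` seconds to a real
#' signal by multiplying its DFT with `exp(-j 2 pi f delay)`. Exact under
#' periodic extension; callers must ensure quiet signal edges when a linear
#' (non-circular) shift is intended.
#'
#' @param x numeric vector.
#' @param delay_s delay in seconds (positive delays shift content later).
#' @param fs_hz sampling rate in Hz.
#' @return numeric vector of the same length.
#' @export
fractional_shift <- function(x, delay_s, fs_hz) {
  n <- length(x)
  f <- signed_freqs(n, fs_hz)
  ph <- exp(-2i * pi * f * delay_s)
  if (n %% 2 == 0) ph[n / 2 + 1] <- Re(ph[n / 2 + 1]) # keep output real
  Re(stats::fft(stats::fft(x) * ph, inverse = TRUE)) / n
}

#' Zero-phase FFT band-pass filter
#'
#' Multiplies the spectrum by a real mask that is exactly zero outside
#' `[f_lo_hz, f_hi_hz]` and rolls off with raised-cosine flanks of width
#' `trans_hz` *inside* the band edges. Zero phase, so inter-channel delays
#' are preserved exactly; applied identically to every channel of a grid.
#'
#' @param x numeric vector or matrix (signals in columns).
#' @param fs_hz sampling rate in Hz.
#' @param f_lo_hz,f_hi_hz band edges in Hz.
#' @param trans_hz transition width in Hz.
#' @return filtered object of the same shape.
#' @export
bandpass_fft <- function(x, fs_hz, f_lo_hz, f_hi_hz, trans_hz = 0.1) {
  if (f_lo_hz < 0 || f_hi_hz <= f_lo_hz || f_hi_hz > fs_hz / 2)
    stop_invalid("band [%g, %g] Hz invalid for fs = %g Hz", f_lo_hz, f_hi_hz, fs_hz)
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  fa <- abs(signed_freqs(n, fs_hz))
  mask <- numeric(n)
  inb <- fa >= f_lo_hz & fa <= f_hi_hz
  mask[inb] <- 1
  tw <- min(trans_hz, (f_hi_hz - f_lo_hz) / 4)
  if (tw > 0) {
    lo_ramp <- inb & fa < f_lo_hz + tw
    hi_ramp <- inb & fa > f_hi_hz - tw
    mask[lo_ramp] <- 0.5 * (1 - cos(pi * (fa[lo_ramp] - f_lo_hz) / tw))
    mask[hi_ramp] <- 0.5 * (1 - cos(pi * (f_hi_hz - fa[hi_ramp]) / tw))
  }
  Y <- stats::mvfft(xm) * mask
  out <- Re(stats::mvfft(Y, inverse = TRUE)) / n
  if (vec) drop(out) else out
}
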