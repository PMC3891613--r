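#' Reference action-potential waveform
#'
#' Samples a zero-mean, band-limited pulse used as the common signal shape
#' `s(n)` that propagates across the electrode grid. The default "biphasic"
#' family is the first derivative of a Gaussian, matching the morphology of
#' surface-recorded uterine action potentials; "triphasic" is the second
#' derivative (Ricker). The pulse is supported on `duration_s` with
#' `sigma = duration_s / 8`, so its tails are truncated at 4 sigma and its
#' spectral energy is concentrated well below `fs_hz / 4`, which keeps
#' sub-sample delays resolvable.
#'
#' @param fs_hz sampling rate in Hz.
#' @param duration_s pulse support in seconds.
#' @param shape waveform family, `"biphasic"` or `"triphasic"`.
#' @return numeric vector of `round(fs_hz * duration_s)` samples, zero mean,
#'   peak absolute amplitude 1.
#' @examples
#' s <- generate_ap_waveform(200, 0.5)
#' length(s)   # 100
#' mean(s)     # ~0
#' @export
generate_ap_waveform <- function(fs_hz, duration_s,
                                 shape = c("biphasic", "triphasic")) {
  shape <- match.arg(shape)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || fs_hz <= 0)
    stop_invalid("fs_hz must be a positive scalar")
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0)
    stop_invalid("duration_s must be a positive scalar")
  n <- round(fs_hz * duration_s)
  if (n < 8)
    stop_invalid("pulse must span at least 8 samples (got %d)", n)
  t <- (seq_len(n) - 0.5) / fs_hz - duration_s / 2
  s <- ap_pulse(t, duration_s, shape)
  s <- s - mean(s)
  s / max(abs(s))
}

# Continuous-time pulse evaluator shared by the sampler above and the grid
# simulator (which evaluates it at fractionally delayed times).
ap_pulse <- function(t, width_s, shape = "biphasic") {
  sigma <- width_s / 8
  u <- t / sigma
  switch(shape,
    biphasic  = -u * exp(-u^2 / 2) * exp(0.5),      # unit peak at u = -1
    triphasic = (1 - u^2) * exp(-u^2 / 2),
    stop_invalid("unknown waveform family '%s'", shape)
  )
}
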