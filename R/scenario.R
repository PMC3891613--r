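#' Simulation scenario for a grid recording
#'
#' Describes a synthetic high-density EHG measurement: grid geometry, sampling,
#' a contraction schedule, and per-contraction ground-truth propagation
#' (conduction-velocity amplitude and incidence angle from the grid's vertical
#' row axis). Within each scheduled contraction the simulator emits a burst of
#' action potentials that propagates as a plane wave; between contractions only
#' noise is present.
#'
#' @param duration_s total recording length in seconds.
#' @param contraction_schedule two-column matrix (or list of length-2 vectors)
#'   of contraction `(onset_s, duration_s)`; contractions must not overlap and
#'   must lie within the recording.
#' @param n_rows,n_cols grid dimensions (default 8 x 8).
#' @param electrode_spacing_cm interelectrode distance d in cm.
#' @param fs_hz sampling rate in Hz.
#' @param true_cv_cm_s conduction-velocity amplitude(s) in cm/s, recycled over
#'   contractions.
#' @param true_angle_rad incidence angle(s) theta in [-pi, pi], measured from
#'   the vertical (row) axis, recycled over contractions.
#' @param spike_rate_hz mean action-potential firing rate within bursts.
#' @param spike_jitter_frac relative jitter of inter-spike intervals (0 for a
#'   strictly periodic burst).
#' @param snr_db signal-to-noise ratio of the additive white Gaussian channel
#'   noise, in dB; `Inf` for noiseless.
#' @param ap_width_s action-potential pulse width in seconds.
#' @param ap_amplitude_uv pulse peak amplitude in microvolt.
#' @param ap_shape waveform family, see [generate_ap_waveform()].
#' @param rng_seed integer seed making the recording bit-reproducible.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(duration_s,
                         contraction_schedule,
                         n_rows = 8, n_cols = 8,
                         electrode_spacing_cm = 0.5,
                         fs_hz = 200,
                         true_cv_cm_s = 8,
                         true_angle_rad = 0,
                         spike_rate_hz = 0.5,
                         spike_jitter_frac = 0.1,
                         snr_db = 10,
                         ap_width_s = 0.1,
                         ap_amplitude_uv = 50,
                         ap_shape = "biphasic",
                         rng_seed = 1L) {
  if (is.list(contraction_schedule))
    contraction_schedule <- do.call(rbind, contraction_schedule)
  sched <- matrix(as.numeric(contraction_schedule), ncol = 2)
  colnames(sched) <- c("onset_s", "duration_s")
  if (n_rows < 2 || n_cols < 2)
    stop_invalid("grid must be at least 2 x 2 (got %d x %d)", n_rows, n_cols)
  if (electrode_spacing_cm <= 0 || fs_hz <= 0 || duration_s <= 0)
    stop_invalid("electrode_spacing_cm, fs_hz and duration_s must be positive")
  if (nrow(sched) > 0) {
    if (any(sched[, 2] <= 0)) stop_invalid("contraction durations must be positive")
    if (any(sched[, 1] < 0) || any(rowSums(sched) > duration_s))
      stop_invalid("contractions must lie within [0, duration_s]")
    o <- order(sched[, 1])
    sched <- sched[o, , drop = FALSE]
    if (nrow(sched) > 1 &&
        any(sched[-1, 1] < (sched[-nrow(sched), 1] + sched[-nrow(sched), 2])))
      stop_invalid("contractions must not overlap")
  }
  k <- max(1L, nrow(sched))
  cv <- rep_len(true_cv_cm_s, k)
  th <- rep_len(true_angle_rad, k)
  if (any(cv <= 0)) stop_invalid("true_cv_cm_s must be positive")
  if (any(th < -pi | th > pi)) stop_invalid("true_angle_rad must lie in [-pi, pi]")
  if (spike_rate_hz <= 0) stop_invalid("spike_rate_hz must be positive")
  if (ap_width_s <= 0) stop_invalid("ap_width_s must be positive")
  if (!is.finite(snr_db) && snr_db < 0) stop_invalid("snr_db must be finite or +Inf")
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    electrode_spacing_cm = electrode_spacing_cm,
    fs_hz = fs_hz, duration_s = duration_s,
    contraction_schedule = sched,
    true_cv_cm_s = cv, true_angle_rad = th,
    spike_rate_hz = spike_rate_hz, spike_jitter_frac = spike_jitter_frac,
    snr_db = snr_db,
    ap_width_s = ap_width_s, ap_amplitude_uv = ap_amplitude_uv,
    ap_shape = ap_shape,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("sim_scenario: %d x %d grid, d = %g cm, fs = %g Hz, %g s\n",
              x$n_rows, x$n_cols, x$electrode_spacing_cm, x$fs_hz, x$duration_s))
  cat(sprintf("  %d contraction(s); CV %s cm/s; angle %s rad; SNR %s dB; seed %d\n",
              nrow(x$contraction_schedule),
              paste(signif(x$true_cv_cm_s, 3), collapse = "/"),
              paste(signif(x$true_angle_rad, 3), collapse = "/"),
              format(x$snr_db), x$rng_seed))
  invisible(x)
}

#' Inter-row / inter-column delays of a plane wave
#'
#' Forward map from a conduction-velocity vector to the per-electrode-step
#' delays: `tau_r = d cos(theta) / CV`, `tau_c = d sin(theta) / CV`.
#'
#' @param cv_cm_s conduction-velocity amplitude in cm/s (> 0).
#' @param angle_rad incidence angle in radians from the vertical (row) axis.
#' @param electrode_spacing_cm interelectrode distance in cm.
#' @return list with `tau_r_s` and `tau_c_s` in seconds.
#' @seealso [delays_to_cv()] for the inverse map.
#' @export
cv_to_delays <- function(cv_cm_s, angle_rad, electrode_spacing_cm) {
  if (any(cv_cm_s <= 0)) stop_invalid("cv_cm_s must be positive")
  list(tau_r_s = electrode_spacing_cm * cos(angle_rad) / cv_cm_s,
       tau_c_s = electrode_spacing_cm * sin(angle_rad) / cv_cm_s)
}
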