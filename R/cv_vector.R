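#' Conduction-velocity vector from plane-wave delays
#'
#' Inverts the forward map `tau_r = d cos(theta)/CV`, `tau_c = d sin(theta)/CV`:
#' amplitude `CV = d / sqrt(tau_r^2 + tau_c^2)` and incidence angle
#' `theta = atan2(tau_c, tau_r)`, measured from the grid's vertical (row) axis
#' (rows increase downward, positive angles counter-clockwise).
#'
#' @param delays a `delay_pair` or list with `tau_r_s`, `tau_c_s` (seconds).
#' @param electrode_spacing_cm interelectrode distance d in cm.
#' @return one-row data.frame of class `cv_vector` with columns
#'   `amplitude_cm_s`, `angle_rad`, `tau_r_s`, `tau_c_s`, `cost`, `converged`,
#'   `excluded`, `reason`. A zero delay vector (infinite velocity) is returned
#'   excluded with reason `"zero-delay"`.
#' @export
delays_to_cv <- function(delays, electrode_spacing_cm) {
  if (electrode_spacing_cm <= 0) stop_invalid("electrode_spacing_cm must be positive")
  tr <- delays$tau_r_s; tc <- delays$tau_c_s
  nrm <- sqrt(tr^2 + tc^2)
  if (nrm == 0) {
    return(structure(data.frame(
      amplitude_cm_s = NA_real_, angle_rad = NA_real_,
      tau_r_s = tr, tau_c_s = tc,
      cost = delays$cost %||% NA_real_,
      converged = delays$converged %||% NA,
      excluded = TRUE, reason = "zero-delay",
      stringsAsFactors = FALSE), class = c("cv_vector", "data.frame")))
  }
  structure(data.frame(
    amplitude_cm_s = electrode_spacing_cm / nrm,
    angle_rad = atan2(tc, tr),
    tau_r_s = tr, tau_c_s = tc,
    cost = delays$cost %||% NA_real_,
    converged = delays$converged %||% NA,
    excluded = FALSE, reason = NA_character_,
    stringsAsFactors = FALSE), class = c("cv_vector", "data.frame"))
}

#' Exclude supra-physiological conduction velocities
#'
#' Marks vectors with amplitude strictly above `max_cv_cm_s` (default
#' 30 cm/s, well above physiological uterine propagation) as excluded with
#' reason `"supra-physiological"`; order and all other rows are untouched.
#'
#' @param cvs data.frame with at least `amplitude_cm_s`, `excluded`, `reason`
#'   columns (e.g. rows of [delays_to_cv()] results).
#' @param max_cv_cm_s exclusion threshold in cm/s (strict inequality).
#' @return the same data.frame with exclusions applied.
#' @export
filter_outliers <- function(cvs, max_cv_cm_s = 30) {
  if (nrow(cvs) == 0) return(cvs)
  hit <- !is.na(cvs$amplitude_cm_s) & cvs$amplitude_cm_s > max_cv_cm_s
  cvs$excluded[hit] <- TRUE
  cvs$reason[hit] <- "supra-physiological"
  cvs
}

#' Window-level CV estimates for a set of contractions
#'
#' Convenience driver: splits each confirmed contraction into overlapping
#' analysis windows, estimates noise-based channel weights and the
#' maximum-likelihood delays per window, converts to CV vectors, and applies
#' the supra-physiological outlier rule. Non-converged windows are marked
#' excluded with reason `"non-converged"`.
#'
#' @param recording a [grid_recording()].
#' @param segments confirmed contraction segments (data.frame with `onset_s`,
#'   `duration_s`).
#' @param window_length_s,overlap_s analysis windowing (defaults 10 s / 5 s).
#' @param search_cfg a [cv_search_config()].
#' @param max_cv_cm_s outlier threshold (default 30 cm/s).
#' @return data.frame, one row per analysis window: `contraction_id`,
#'   `start_s`, `tau_r_s`, `tau_c_s`, `cv_cm_s` (alias of amplitude),
#'   `amplitude_cm_s`, `angle_rad`, `cost`, `converged`, `excluded`, `reason`.
#' @export
estimate_contraction_cv <- function(recording, segments,
                                    window_length_s = 10, overlap_s = 5,
                                    search_cfg = cv_search_config(),
                                    max_cv_cm_s = 30) {
  rows <- list()
  for (i in seq_len(nrow(segments))) {
    wins <- segment_contraction(segments[i, ], recording,
                                window_length_s = window_length_s,
                                overlap_s = overlap_s,
                                f_band_hz = search_cfg$f_band_hz,
                                contraction_id = i)
    for (win in wins) {
      cv <- tryCatch({
        dp <- estimate_delays(win, weights = NULL, search_cfg = search_cfg)
        v <- delays_to_cv(dp, recording$electrode_spacing_cm)
        if (!isTRUE(dp$converged) && !v$excluded) {
          v$excluded <- TRUE
          v$reason <- "non-converged"
        }
        v
      }, ehgcv_degenerate_input = function(e) {
        structure(data.frame(amplitude_cm_s = NA_real_, angle_rad = NA_real_,
                             tau_r_s = NA_real_, tau_c_s = NA_real_,
                             cost = NA_real_, converged = FALSE,
                             excluded = TRUE, reason = "degenerate-window",
                             stringsAsFactors = FALSE),
                  class = c("cv_vector", "data.frame"))
      })
      cv$contraction_id <- i
      cv$start_s <- win$start_s
      rows[[length(rows) + 1]] <- cv
    }
  }
  if (!length(rows)) {
    out <- data.frame(contraction_id = integer(0), start_s = numeric(0),
                      tau_r_s = numeric(0), tau_c_s = numeric(0),
                      cv_cm_s = numeric(0), amplitude_cm_s = numeric(0),
                      angle_rad = numeric(0), cost = numeric(0),
                      converged = logical(0), excluded = logical(0),
                      reason = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- filter_outliers(out, max_cv_cm_s)
  out$cv_cm_s <- out$amplitude_cm_s
  rownames(out) <- NULL
  out[, c("contraction_id", "start_s", "tau_r_s", "tau_c_s", "cv_cm_s",
          "amplitude_cm_s", "angle_rad", "cost", "converged",
          "excluded", "reason")]
}
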