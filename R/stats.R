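#' Average a set of conduction-velocity vectors
#'
#' The "average CV vector" is a true vector mean: the Cartesian components
#' `(CV cos theta, CV sin theta)` of all non-excluded vectors are averaged
#' and converted back to amplitude and angle. The scalar mean of the
#' amplitudes is reported alongside (`amp_scalar_cm_s`) because group
#' comparisons may be run on either. Opposite vectors can cancel; a resultant
#' whose amplitude is negligible relative to the mean amplitude is flagged
#' degenerate (excluded, reason `"degenerate-cancellation"`).
#'
#' @param cvs data.frame with `amplitude_cm_s`, `angle_rad`, `excluded`.
#' @return one-row data.frame: `amplitude_cm_s`, `angle_rad`,
#'   `amp_scalar_cm_s`, `circ_var` (circular variance of the angles, a
#'   descriptive dispersion measure), `n_used`, `excluded`, `reason`; `NULL`
#'   if no usable vectors (signaled via a `"ehgcv_no_usable_vectors"`
#'   condition message, not an error).
#' @export
average_cv_vectors <- function(cvs) {
  use <- !cvs$excluded & !is.na(cvs$amplitude_cm_s)
  if (!any(use)) {
    message("no usable (non-excluded) CV vectors; dropping")
    return(NULL)
  }
  amp <- cvs$amplitude_cm_s[use]
  ang <- cvs$angle_rad[use]
  vx <- mean(amp * cos(ang))
  vy <- mean(amp * sin(ang))
  res <- sqrt(vx^2 + vy^2)
  degen <- res < 1e-9 * mean(amp)
  data.frame(
    amplitude_cm_s = res,
    angle_rad = atan2(vy, vx),
    amp_scalar_cm_s = mean(amp),
    circ_var = 1 - sqrt(mean(cos(ang))^2 + mean(sin(ang))^2),
    n_used = sum(use),
    excluded = degen,
    reason = if (degen) "degenerate-cancellation" else NA_character_,
    stringsAsFactors = FALSE)
}

#' Per-contraction average CV vector
#'
#' Vector mean of the window-level CV vectors of one contraction; see
#' [average_cv_vectors()].
#' @param windows data.frame of window-level CV vectors.
#' @export
average_contraction <- function(windows) average_cv_vectors(windows)

#' Per-patient average CV vector
#'
#' Identical contract to [average_contraction()], one aggregation level up:
#' vector mean of a patient's per-contraction vectors, making the result
#' independent of how many windows or contractions were analyzed.
#' @param contractions data.frame of per-contraction CV vectors.
#' @export
average_patient <- function(contractions) average_cv_vectors(contractions)

#' Aggregate window-level CVs to per-patient records
#'
#' Averages window vectors within contractions, then contraction vectors
#' within patients, and assigns each patient to the labor group if delivery
#' occurred within `labor_cutoff_h` hours of the measurement.
#'
#' @param window_cvs data.frame with columns `patient_id`, `contraction_id`,
#'   `amplitude_cm_s`, `angle_rad`, `excluded`.
#' @param patients data.frame with `patient_id`, `hours_to_delivery`.
#' @param labor_cutoff_h classification cutoff in hours (default 24).
#' @return data.frame, one row per patient with usable data: `patient_id`,
#'   `group` (`"labor"`/`"nonlabor"`), `cv_cm_s` (vector-mean amplitude),
#'   `cv_scalar_cm_s`, `angle_rad`, `circ_var`, `n_contractions`.
#' @export
build_patient_records <- function(window_cvs, patients, labor_cutoff_h = 24) {
  out <- list()
  for (pid in unique(window_cvs$patient_id)) {
    pw <- window_cvs[window_cvs$patient_id == pid, , drop = FALSE]
    per_con <- list()
    for (cid in unique(pw$contraction_id)) {
      avg <- average_cv_vectors(pw[pw$contraction_id == cid, , drop = FALSE])
      if (!is.null(avg) && !avg$excluded) per_con[[length(per_con) + 1]] <- avg
    }
    if (!length(per_con)) next
    pavg <- average_cv_vectors(do.call(rbind, per_con))
    if (is.null(pavg) || pavg$excluded) next
    htd <- patients$hours_to_delivery[match(pid, patients$patient_id)]
    out[[length(out) + 1]] <- data.frame(
      patient_id = pid,
      group = if (!is.na(htd) && htd <= labor_cutoff_h) "labor" else "nonlabor",
      cv_cm_s = pavg$amplitude_cm_s,
      cv_scalar_cm_s = pavg$amp_scalar_cm_s,
      angle_rad = pavg$angle_rad,
      circ_var = pavg$circ_var,
      n_contractions = length(per_con),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(patient_id = character(0),
                                      group = character(0),
                                      cv_cm_s = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Levene's test for equality of variances
#'
#' Classic Levene statistic: one-way ANOVA F test on the absolute deviations
#' of each observation from its group center (`"mean"` for Levene's original
#' test, `"median"` for the Brown-Forsythe variant).
#'
#' @param values numeric vector.
#' @param groups factor-like of the same length (2+ levels).
#' @param center `"mean"` or `"median"`.
#' @return list with `statistic` (F), `df` (c(k-1, n-k)), `p_value`.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop_invalid("need at least 2 groups")
  cfun <- if (center == "mean") mean else stats::median
  z <- abs(values - stats::ave(values, groups, FUN = cfun))
  k <- nlevels(groups)
  n <- length(z)
  zbar <- mean(z)
  zg <- tapply(z, groups, mean)
  ng <- tabulate(groups)
  ss_between <- sum(ng * (zg - zbar)^2)
  ss_within <- sum((z - stats::ave(z, groups, FUN = mean))^2)
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(statistic = f, df = c(k - 1, n - k),
       p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

#' Labor vs nonlabor comparison of per-patient conduction velocities
#'
#' Runs the group comparison on per-patient mean CV amplitudes: Shapiro-Wilk
#' normality test per group, Levene's test for equal variances across groups,
#' and a two-sided independent-samples t-test (pooled variance). Significance
#' is declared when the t-test p-value falls below `alpha`.
#'
#' @param patients a [build_patient_records()] result (or data.frame with
#'   `group` in `{"labor", "nonlabor"}` and the chosen amplitude column).
#' @param alpha significance level (default 0.05).
#' @param amplitude which per-patient amplitude enters the tests:
#'   `"vector"` (vector-mean amplitude, column `cv_cm_s`, default) or
#'   `"scalar"` (mean of amplitudes, column `cv_scalar_cm_s`).
#' @return object of class `group_comparison` with group means/SDs, the three
#'   p-values, per-group Shapiro p-values, `alpha`, and `significant`.
#' @export
compare_groups <- function(patients, alpha = 0.05,
                           amplitude = c("vector", "scalar")) {
  amplitude <- match.arg(amplitude)
  col <- if (amplitude == "vector") "cv_cm_s" else "cv_scalar_cm_s"
  if (!col %in% names(patients)) stop_invalid("column '%s' not found", col)
  lab <- patients[[col]][patients$group == "labor"]
  non <- patients[[col]][patients$group == "nonlabor"]
  if (length(lab) < 2 || length(non) < 2)
    stop_invalid("need at least 2 patients per group (got %d labor, %d nonlabor)",
                 length(lab), length(non))
  sh_lab <- if (length(lab) >= 3) stats::shapiro.test(lab)$p.value else NA_real_
  sh_non <- if (length(non) >= 3) stats::shapiro.test(non)$p.value else NA_real_
  lev <- levene_test(c(lab, non),
                     rep(c("labor", "nonlabor"), c(length(lab), length(non))))
  tt <- stats::t.test(lab, non, var.equal = TRUE)
  structure(list(
    labor_mean_cm_s = mean(lab), labor_sd_cm_s = stats::sd(lab),
    nonlabor_mean_cm_s = mean(non), nonlabor_sd_cm_s = stats::sd(non),
    n_labor = length(lab), n_nonlabor = length(non),
    shapiro_p = min(sh_lab, sh_non, na.rm = TRUE),
    shapiro_p_labor = sh_lab, shapiro_p_nonlabor = sh_non,
    levene_p = lev$p_value,
    ttest_p = tt$p.value, t_statistic = unname(tt$statistic),
    alpha = alpha, significant = tt$p.value < alpha,
    amplitude = amplitude
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Labor vs nonlabor comparison of per-patient CV amplitude\n")
  cat(sprintf("  labor    : %5.2f +/- %.2f cm/s (n = %d)\n",
              x$labor_mean_cm_s, x$labor_sd_cm_s, x$n_labor))
  cat(sprintf("  nonlabor : %5.2f +/- %.2f cm/s (n = %d)\n",
              x$nonlabor_mean_cm_s, x$nonlabor_sd_cm_s, x$n_nonlabor))
  cat(sprintf("  Shapiro-Wilk p = %.3g (labor %.3g, nonlabor %.3g)\n",
              x$shapiro_p, x$shapiro_p_labor, x$shapiro_p_nonlabor))
  cat(sprintf("  Levene p = %.3g; t = %.3f, p = %.3g (%ssignificant at alpha = %g)\n",
              x$levene_p, x$t_statistic, x$ttest_p,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}
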