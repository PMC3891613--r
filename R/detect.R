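#' Detect contractions from the estimated intrauterine pressure
#'
#' Adaptive thresholding of Psi in 60 s windows with 50% overlap. Within each
#' window the local baseline is the lower quartile of Psi and the local spread
#' is `k_sigma` times the MAD of the sub-median frames (a burst occupying up
#' to three quarters of a window therefore cannot inflate the baseline, and
#' with 50% window overlap every frame is covered by at least one window in
#' which the burst is a minority); the spread term is floored at 5% of the
#' global Psi range to avoid zero-spread pathologies on quiet stretches. A
#' frame's effective threshold is the minimum over the windows covering it,
#' and supra-threshold runs become candidate contractions. Each run's
#' onset/offset is then refined to the linearly interpolated crossing of the
#' quarter-height level of its Psi bump (robust both to mid-burst Psi dips
#' and to elevated-noise frames attached to the run at the lower detection
#' threshold), runs closer than one frame hop are merged, and runs shorter
#' than `min_duration_s` are dropped.
#'
#' @param iup an [estimate_iup()] result.
#' @param window_s adaptive-threshold window length (default 60 s).
#' @param min_duration_s minimum contraction duration kept (default 30 s).
#' @param k_sigma threshold factor on the robust spread (default 3).
#' @param spread_floor_frac floor on the spread term as a fraction of the
#'   global Psi range (default 0.05).
#' @param prominence validation factor of the double-threshold rule: a run is
#'   kept only if its peak exceeds the global baseline by at least
#'   `prominence` times the global spread term (default 3).
#' @return data.frame of class `contraction_segments` with columns `onset_s`,
#'   `duration_s`, `peak_psi`, `confirmed_by` (NA until
#'   [confirm_contractions()]), disjoint and ordered by onset.
#' @export
detect_contractions <- function(iup, window_s = 60, min_duration_s = 30,
                                k_sigma = 3, spread_floor_frac = 0.05,
                                prominence = 3) {
  if (!inherits(iup, "iup_estimate")) stop_invalid("iup must be an iup_estimate")
  psi <- iup$psi
  tf <- iup$frame_times_s
  if (length(psi) == 0) stop_invalid("empty iup")
  span <- tf[length(tf)] - tf[1]
  if (span < 2 * window_s)
    stop_invalid("iup spans %.1f s; need at least 2 x %g s", span, window_s)

  floor_abs <- spread_floor_frac * (max(psi) - min(psi))
  step <- window_s / 2
  starts <- seq(tf[1], max(tf[1], tf[length(tf)] - window_s), by = step)
  thr_f <- rep(Inf, length(psi))
  for (s0 in starts) {
    in_w <- tf >= s0 & tf <= s0 + window_s
    if (sum(in_w) < 4) next
    loc <- psi[in_w]
    base <- unname(stats::quantile(loc, 0.25))
    low <- loc[loc <= stats::median(loc)]
    thr <- base + max(k_sigma * stats::mad(low), floor_abs)
    thr_f[in_w] <- pmin(thr_f[in_w], thr)
  }
  flagged <- is.finite(thr_f) & psi > thr_f

  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  begs <- ends - runs$lengths + 1L
  seg_idx <- which(runs$values)
  out <- list()
  base <- if (any(!flagged)) stats::median(psi[!flagged]) else min(psi)
  # double-threshold validation level: runs are *seeded* by the low adaptive
  # threshold (which fixes their extent), but their peak must clear a high
  # global level, or sustained low-level noise excursions would qualify
  low_spread <- stats::mad(psi[psi <= stats::median(psi)])
  valid_level <- base + prominence * max(k_sigma * low_spread, floor_abs)
  for (j in seg_idx) {
    i0 <- begs[j]; i1 <- ends[j]
    peak <- max(psi[i0:i1])
    if (peak < valid_level) next
    # boundaries at quarter height of the run's bump: low enough to be
    # unbiased by mid-burst Psi dips, high enough that elevated-noise frames
    # hanging onto the run at the detection threshold do not drag the edge out
    level <- base + 0.25 * (peak - base)
    above <- which(psi[i0:i1] >= level) + i0 - 1L
    onset <- .cross_time(psi, tf, above[1], level, dir = -1L)
    offset <- .cross_time(psi, tf, above[length(above)], level, dir = +1L)
    dur <- offset - onset
    if (dur < min_duration_s) next
    out[[length(out) + 1]] <- data.frame(
      onset_s = onset, duration_s = dur, peak_psi = peak,
      confirmed_by = NA_character_, stringsAsFactors = FALSE)
  }
  segs <- if (length(out)) do.call(rbind, out) else
    data.frame(onset_s = numeric(0), duration_s = numeric(0),
               peak_psi = numeric(0), confirmed_by = character(0),
               stringsAsFactors = FALSE)
  segs <- .merge_segments(segs, gap_s = iup$frame_hop_s)
  if (nrow(segs) > 1) {
    ends <- segs$onset_s + segs$duration_s
    stopifnot(!is.unsorted(segs$onset_s),
              all(segs$onset_s[-1] >= ends[-length(ends)]))
  }
  class(segs) <- c("contraction_segments", "data.frame")
  segs
}

# Interpolated time at which psi falls through `level`, walking outward from
# frame `i` (which satisfies psi[i] >= level) in direction `dir`.
.cross_time <- function(psi, tf, i, level, dir) {
  j <- i
  while (j + dir >= 1 && j + dir <= length(psi) && psi[j + dir] >= level)
    j <- j + dir
  k <- j + dir
  if (k < 1 || k > length(psi) || psi[j] == psi[k]) return(tf[j])
  frac <- (psi[j] - level) / (psi[j] - psi[k])
  frac <- min(1, max(0, frac))
  tf[j] + frac * (tf[k] - tf[j])
}

.merge_segments <- function(segs, gap_s) {
  if (nrow(segs) < 2) return(segs)
  segs <- segs[order(segs$onset_s), , drop = FALSE]
  keep <- segs[1, , drop = FALSE]
  for (i in 2:nrow(segs)) {
    last <- nrow(keep)
    if (segs$onset_s[i] <= keep$onset_s[last] + keep$duration_s[last] + gap_s) {
      new_end <- max(keep$onset_s[last] + keep$duration_s[last],
                     segs$onset_s[i] + segs$duration_s[i])
      keep$duration_s[last] <- new_end - keep$onset_s[last]
      keep$peak_psi[last] <- max(keep$peak_psi[last], segs$peak_psi[i])
    } else {
      keep <- rbind(keep, segs[i, , drop = FALSE])
    }
  }
  rownames(keep) <- NULL
  keep
}

#' Confirm detected contractions against external annotations
#'
#' Keeps a segment iff it overlaps a tocodynamometer mark interval (any
#' nonzero intersection) or a maternal-perception instant falls within the
#' segment extended by `slack_s` on both sides. `confirmed_by` records which
#' criteria fired (`"toco"`, `"perception"`, or `"toco+perception"`).
#'
#' @param segments a [detect_contractions()] result (or compatible data.frame).
#' @param toco_marks two-column matrix of `(onset_s, duration_s)` intervals.
#' @param perception_marks numeric vector of annotated instants (s).
#' @param slack_s tolerance around the segment for perception instants
#'   (default 30 s, about half a typical contraction).
#' @return the confirmed subset, same columns, `confirmed_by` filled in.
#' @export
confirm_contractions <- function(segments, toco_marks, perception_marks,
                                 slack_s = 30) {
  toco_marks <- matrix(as.numeric(toco_marks), ncol = 2)
  perception_marks <- as.numeric(perception_marks)
  if (nrow(segments) == 0) return(segments)
  conf <- character(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    a <- segments$onset_s[i]; b <- a + segments$duration_s[i]
    by_toco <- nrow(toco_marks) > 0 &&
      any(pmin(b, toco_marks[, 1] + toco_marks[, 2]) - pmax(a, toco_marks[, 1]) > 0)
    by_perc <- length(perception_marks) > 0 &&
      any(perception_marks >= a - slack_s & perception_marks <= b + slack_s)
    conf[i] <- paste(c(if (by_toco) "toco", if (by_perc) "perception"),
                     collapse = "+")
  }
  out <- segments[conf != "", , drop = FALSE]
  out$confirmed_by <- conf[conf != ""]
  rownames(out) <- NULL
  out
}
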