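---
title: "Estimating uterine conduction velocity from high-density EHG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating uterine conduction velocity from high-density EHG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehgcv)
```

## The problem

Uterine contractions are driven by action potentials (APs) that originate in
pacemaker cells and propagate from cell to cell through gap junctions. As
delivery approaches, electrical connectivity in the myometrium increases and
APs propagate faster and more coherently. The electrohysterogram (EHG) — a
noninvasive abdominal recording of this activity — therefore carries a
candidate predictor of imminent delivery: the conduction velocity (CV) of the
propagating APs. Unlike skeletal muscle, the uterus has no anatomically fixed
propagation direction, so the CV must be estimated as a two-dimensional
vector, which requires a two-dimensional sensor: here an 8 × 8 high-density
electrode grid, plus one bipolar electrode pair used for contraction timing.

`ehgcv` implements the complete automated analysis chain: contraction
detection from the bipolar channel, maximum-likelihood (ML) estimation of the
CV vector on the grid within contractions, exclusion of supra-physiological
estimates, and a labor vs nonlabor group comparison of per-patient mean CV
amplitudes. Because clinical grid recordings are not generally available, the
package also contains a first-class simulator that generates grid recordings
obeying the same signal model with known ground truth; every stage of the
pipeline is validated against it.

## Signal model

Within a contraction, every grid channel is assumed to record the same AP
waveform `s(n)`, delayed linearly in the electrode indices (plane-wave
propagation across a small grid):

```
x_rc(n) = s(n - (r-1) tau_r - (c-1) tau_c) + w_rc(n),
```

where `tau_r` and `tau_c` are the inter-row and inter-column delays and
`w_rc` is white Gaussian channel noise. For interelectrode distance `d`, the
delays encode the CV vector through

```
tau_r = d cos(theta) / CV,      tau_c = d sin(theta) / CV,
```

with amplitude `CV` and incidence angle `theta` measured from the grid's
vertical (row) axis, rows increasing downward (toward the cervix as mounted)
and positive angles counter-clockwise. `delays_to_cv()` inverts this map:
`CV = d / sqrt(tau_r^2 + tau_c^2)`, `theta = atan2(tau_c, tau_r)`.

## Contraction detection

The bipolar channel's spectrogram `rho(n, f)` (Hann window 20 s, hop 5 s,
zero-padded to a bin spacing of 0.025 Hz) is reduced to the **unnormalized
first spectral moment** in the 0.3–0.8 Hz band,

```
Psi(n) = sum_{f in [0.3, 0.8]} f * rho(n, f),
```

a validated surrogate of intrauterine pressure used here *only* for timing —
no amplitude calibration is attempted. The band captures the repetition rate
of AP spikes within a burst; between bursts Psi falls to the in-band noise
floor.

Detection uses a double-threshold rule, adaptive in 60 s windows with 50%
overlap:

* **Low (seeding) threshold, per window**: lower quartile of Psi plus
  `k_sigma` (default 3) times the MAD of the sub-median frames, floored at 5%
  of the global Psi range. A frame's effective threshold is the minimum over
  the windows covering it. Using the lower quartile and sub-median spread —
  rather than the median and full MAD — matters: a contraction can occupy
  more than half of a 60 s window, in which case median-based statistics sit
  on the burst and the detector goes blind exactly where the signal is.
  With 50% overlap every frame is also covered by a window in which the burst
  is a minority.
* **High (validation) level, global**: baseline (median of sub-threshold
  frames) plus 3 × the global spread term. A run of supra-threshold frames is
  kept only if its peak clears this level. This is the classic
  double-threshold EMG burst detector: the low threshold fixes the *extent*
  of a burst, the high one decides its *existence*, rejecting sustained
  low-level noise excursions (in-band noise power is heavily correlated
  across the 75%-overlapping frames and wanders on 20–40 s scales).

Run boundaries are refined to the linearly interpolated crossings of the
quarter-height level of the run's Psi bump. Quarter height is a deliberate
compromise: half-height crossings are unbiased for a rectangular burst
smeared by the 20 s analysis window, but real (and simulated) bursts show
within-burst Psi dips below half height that truncate the segment; at quarter
height the boundary is robust to those dips and to elevated-noise frames
clinging to the run at the seeding threshold, at the cost of a small (~5 s)
early-onset bias — well inside the 10 s accuracy the pipeline is validated
to. Runs shorter than 30 s are dropped; runs separated by at most one frame
hop are merged.

Detections are then **confirmed** against external annotations: a segment is
kept if it overlaps a tocodynamometer interval or if a maternal-perception
instant falls within ±30 s of it (perceptions are instants, so a tolerance is
unavoidable; 30 s is about half a typical contraction).

## ML delay estimation

Within each confirmed contraction, 10 s analysis windows advancing by 5 s
(i.e. 5 s overlap — the overlap is the anchored choice; 10 s is long enough
to contain several APs at physiological firing rates and short enough to
track within-burst CV changes) are extracted and band-pass filtered
0.3–5 Hz with a zero-phase FFT mask applied identically to all channels, so
inter-channel delays are untouched while drift and out-of-band noise are
removed.

Under white Gaussian noise, ML estimation of `(tau_r, tau_c)` is the
minimization of the weighted spectral residual

```
E^2(tau_r, tau_c) = (2/N) sum_rc w_rc sum_{f=0}^{N/2-1}
                    | X_rc(f) - S(f) e^{-j 2 pi f [(r-1) tau_r + (c-1) tau_c]} |^2 ,
```

where `S(f)` is the reference-shape spectrum and the weights `w_rc` are
inversely proportional to the estimated channel noise (normalized to mean 1;
dead channels get weight 0). Working in the frequency domain makes the delays
continuous parameters — estimation has no sampling-resolution limit. Two
facts structure the optimizer:

* Given the delays, the optimal `S(f)` has a closed form: the weighted mean
  of the channel spectra re-aligned to a common origin
  (`estimate_reference_shape()`).
* With that optimum substituted, minimizing `E^2` is *maximizing the steered
  coherent power* `sum_f |sum_rc w_rc X_rc(f) e^{+j phi_rc(f)}|^2` — a
  delay-and-sum beamformer over the 2-D delay plane.

`estimate_delays()` therefore runs: (i) an exhaustive coarse scan of the
steered power over `[-tau_max, tau_max]^2` with `tau_max = d / cv_min`
(default `cv_min` 1 cm/s; slower propagation is treated as non-propagating)
at a 20 ms step — safe because the 0.3–5 Hz band limits the autocorrelation
main lobe to about 0.2 s; (ii) a 5× local lattice refinement;
(iii) Nelder–Mead continuous minimization; then channel weights are
re-estimated from the residual variances about the re-aligned shape (the
first iteration's weights come from the power above 10 Hz, which for
band-limited EHG pulses is pure noise floor) and the minimization repeats
until the delay update falls below `tol_s` (1e-5 s) or `max_iter` (20) is
reached. Non-converged windows are flagged and excluded from averaging.

Estimated vectors with amplitude strictly above 30 cm/s — beyond the
physiological range reported for myometrium — are marked excluded
(`filter_outliers()`); this also serves as a proxy rejection of windows
whose activity does not propagate as a plane wave.

## Group statistics

Window vectors are averaged to one vector per contraction and then one per
patient ("average CV vector" is read as a true vector mean of the Cartesian
components; the scalar mean of amplitudes is computed alongside, and a switch
in `compare_groups()` selects which enters the tests, vector being the
default). Per-patient aggregation makes the comparison independent of how
many windows or contractions each patient contributed. Patients delivering
within 24 h are the labor group. The comparison runs Shapiro–Wilk per group
(the summary p is the minimum of the two), Levene's test (classic, mean
centers; implemented directly since no dedicated package is available) across
groups, and a two-sided pooled-variance t-test, all at alpha = 0.05. Angle
dispersion is reported descriptively as a per-patient circular variance; no
circular test is run.

## The simulator and what a green test establishes

`generate_grid_recording()` realizes the plane-wave model exactly: spikes are
placed inside each scheduled contraction (jittered intervals at
`spike_rate_hz`, default 0.5 Hz), and every channel evaluates a closed-form
Gaussian-derivative pulse (default width 0.1 s, peak 50 µV) at its delayed
sample times. Evaluating the analytic waveform at shifted times realizes
*fractional* delays with zero interpolation error — strictly better than the
FFT phase-shift alternative, which is only exact under periodic extension.
Spikes keep a margin of half a pulse width plus the full grid delay span from
the contraction edges, so every channel's burst lies inside the scheduled
interval; a schedule too short for the delay span is rejected. White Gaussian
noise is added per channel at the requested SNR (defined against the mean
clean power; generated recordings match the request within 0.5 dB). The
bipolar channel is a virtual differential pair offset by a fixed 0.3 s along
the propagation path — a raw burst difference, not an amplitude envelope,
because the 0.3–0.8 Hz detection band captures the spike repetition rate of
the raw EHG, which an envelope (fluctuating on contraction time scales)
would not contain. Tocodynamometer marks copy the schedule and perception
marks sit at contraction midpoints.

The cohort presets (`make_fixture("labor-like")` / `"nonlabor-like"`, and the
cohort in `scripts/acceptance.R`) draw per-contraction CVs near 8.65 and
5.30 cm/s respectively (the reported group means, used as simulation inputs),
use 0.3 s APs — the slower end of surface-recorded uterine spikes, whose
repetition content actually reaches the detection band at 200 Hz sampling —
and give each patient one underlying propagation direction with 30° scatter
across contractions: with i.i.d. uniform directions the per-patient *vector*
mean would collapse toward zero, contradicting the stable per-patient
amplitudes the method is meant to recover.

What the simulator does *not* emulate: volume-conductor and tissue-layer
filtering, electrode-skin impedance variation, maternal/fetal ECG and
respiration artifacts, non-planar (curved or point-source) wavefronts, and
within-window CV changes. A green test suite therefore establishes that the
estimator correctly and robustly inverts the stated plane-wave model under
white noise — not that the full clinical measurement chain is solved.

## Numerical choices and degenerate inputs

* Sampling rate (200 Hz), interelectrode distance (0.5 cm) and grid size are
  configuration, never hard-coded; defaults give inter-electrode delays of
  1.7–50 ms for physiological CVs, comfortably resolvable sub-sample.
* The spectrogram is normalized so each frame's one-sided power sums to the
  frame's mean power (Parseval); Psi's absolute scale cancels out of the
  detector.
* The band-pass mask is exactly zero outside the band, so restricting
  spectral sums to in-band bins during the delay search is exact, not an
  approximation.
* A zero delay vector (infinite velocity) yields an excluded CV vector with
  reason `"zero-delay"`; all-dead channel windows raise a degenerate-input
  error; contraction-average vectors whose resultant is negligible relative
  to the mean amplitude (opposite directions cancelling) are flagged
  `"degenerate-cancellation"` and dropped from patient means with a message,
  not an error.
* The 30 cm/s outlier boundary is strict (`>`): exactly 30 cm/s is retained.
* EDF export quantizes to 16 bits over each channel's range (relative error
  about 1.5e-5); fs must be an integer and trailing partial seconds are
  truncated. Electrode spacing, annotations and ground truth travel in a JSON
  sidecar since EDF cannot carry them.
* Determinism: every stochastic step derives from an explicit seed
  (`rng_seed` in scenarios, `--seed` in the CLI and acceptance script), and
  the generator restores the caller's RNG state.

## Known limitations

The plane-wave model is the analysis assumption, not a fact about every
contraction; windows where propagation is absent or non-linear are only
caught indirectly by the 30 cm/s rule and the convergence flag. The detector
was tuned for burst-to-baseline Psi contrasts of roughly 3× and above
(10 dB channel SNR with in-band spike content); recordings whose spike
energy lies mostly outside 0.3–0.8 Hz will detect poorly, as will very short
(<30 s) contractions, by design. Levene's test uses the classic mean-centered
form; the Brown–Forsythe variant is available via `center = "median"`.
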