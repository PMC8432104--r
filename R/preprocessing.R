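#' High-pass filter raw sEMG
#'
#' Zero-phase 2nd-order Butterworth high-pass (20 Hz cutoff per pass) that
#' removes movement artifacts and electrode drift. The spectral features are
#' computed on this signal, before rectification.
#'
#' @param emg Raw sEMG trace (uniformly sampled).
#' @param fs Sampling frequency (Hz, default 1000).
#' @param cutoff Cutoff frequency (Hz, default 20).
#' @return Filtered trace, same length.
#' @export
highpass_emg <- function(emg, fs = 1000, cutoff = 20) {
  if (length(emg) < 13L)
    stop("EMG trace too short to filter (need > 12 samples)")
  zero_phase_butter(emg, fs, cutoff, "high")
}

#' Full-wave rectify and subtract pre-onset background
#'
#' Rectifies the high-passed sEMG and subtracts the mean rectified level of
#' the `baseline_window` seconds immediately preceding movement onset.
#' Negative values after subtraction are clipped to zero so the envelope and
#' integrated area stay non-negative.
#'
#' @param emg_hp High-passed sEMG trace.
#' @param t_onset Movement onset time (s).
#' @param fs Sampling frequency (Hz).
#' @param baseline_window Background window length before onset (s).
#' @return List: `x` (rectified, debiased trace) and `background` (the
#'   subtracted mean level b).
#' @export
rectify_debias <- function(emg_hp, t_onset, fs = 1000, baseline_window = 0.5) {
  i_on <- round(t_onset * fs) + 1L
  i0 <- i_on - round(baseline_window * fs)
  if (i0 < 1L)
    stop(sprintf("insufficient pre-onset data: need %.3f s before onset",
                 baseline_window))
  r <- abs(emg_hp)
  b <- mean(r[i0:(i_on - 1L)])
  list(x = pmax(r - b, 0), background = b)
}

#' Linear-envelope of rectified sEMG
#'
#' Zero-phase (2-pass) 2nd-order Butterworth low-pass at 10 Hz applied to
#' the rectified, debiased signal.
#'
#' @param rectified Non-negative rectified trace (or the `$x` of
#'   [rectify_debias()]).
#' @param fs Sampling frequency (Hz).
#' @param cutoff Cutoff frequency (Hz, default 10).
#' @return Envelope trace, same length.
#' @export
envelope_emg <- function(rectified, fs = 1000, cutoff = 10) {
  if (length(rectified) < 13L) stop("trace too short to filter")
  zero_phase_butter(rectified, fs, cutoff, "low")
}

#' Integrated envelope area per movement segment
#'
#' Trapezoidal integral of the envelope over each half-cycle segment
#' (units: signal-units times seconds).
#'
#' @param env Envelope trace.
#' @param segments A `segment_set` from [build_segments()].
#' @param fs Sampling frequency (Hz).
#' @return `segments` with an added `area` column.
#' @export
segment_area <- function(env, segments, fs = 1000) {
  n <- length(env)
  t_max <- (n - 1) / fs
  if (any(segments$t_start < 0) || any(segments$t_end > t_max + 1e-9))
    stop("segment outside trace span")
  area <- vapply(seq_len(nrow(segments)), function(i) {
    i0 <- round(segments$t_start[i] * fs) + 1L
    i1 <- min(round(segments$t_end[i] * fs) + 1L, n)
    y <- env[i0:i1]
    sum((head(y, -1) + tail(y, -1)) / 2) / fs
  }, numeric(1))
  out <- segments
  out$area <- area
  out
}
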