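#' Low-pass filter a knee-angle trace
#'
#' Zero-lag (forward-backward) 2nd-order Butterworth low-pass at 5 Hz, the
#' standard kinematic smoothing applied before event detection.
#'
#' @param angle Numeric angle trace (degrees), uniformly sampled.
#' @param fs Sampling frequency (Hz, default 200).
#' @param cutoff Cutoff frequency (Hz, default 5).
#' @return Filtered trace, same length.
#' @export
filter_angle <- function(angle, fs = 200, cutoff = 5) {
  if (length(angle) < 13L)
    stop("angle trace too short to filter (need > 12 samples)")
  zero_phase_butter(angle, fs, cutoff, "low")
}

#' Detect movement onset and flexion/extension peaks
#'
#' Onset is the first time the absolute angular velocity (central
#' difference) exceeds 5\% of its global peak and stays above it for at
#' least 50 ms. Peaks are alternating local extrema of the filtered angle
#' whose prominence is at least 10\% of the total angular range.
#'
#' @param angle_filtered Filtered angle trace (degrees).
#' @param fs Sampling frequency (Hz).
#' @param onset_frac Velocity threshold as a fraction of peak speed.
#' @param onset_hold_s Required hold time above threshold (s).
#' @param prominence_frac Minimum peak prominence as a fraction of range.
#' @return An `event_table`: `t_onset`, `ext_peaks`, `flex_peaks` (s),
#'   `n_cycles` (complete cycles detected).
#' @export
detect_events <- function(angle_filtered, fs = 200, onset_frac = 0.05,
                          onset_hold_s = 0.05, prominence_frac = 0.10) {
  x <- angle_filtered
  n <- length(x)
  if (n < 10L) stop("angle trace too short for event detection")
  rng <- diff(range(x))
  if (rng < .Machine$double.eps^0.25 || rng < 1e-6)
    stop("no movement detected: angle trace is flat")
  # central-difference velocity
  v <- c(x[2L] - x[1L], (x[3L:n] - x[1L:(n - 2L)]) / 2, x[n] - x[n - 1L]) * fs
  speed <- abs(v)
  thr <- onset_frac * max(speed)
  hold <- max(1L, round(onset_hold_s * fs))
  above <- speed > thr
  onset_idx <- NA_integer_
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= hold)
  if (length(ok) == 0L) stop("no movement detected: velocity never sustained")
  onset_idx <- starts[ok[1L]]
  t_onset <- (onset_idx - 1L) / fs

  ext <- find_extrema(x, rng * prominence_frac)
  if (nrow(ext) == 0L) stop("no movement detected: no prominent extrema")
  # enforce alternation: collapse runs of same-type extrema to the strongest
  keep <- logical(nrow(ext))
  i <- 1L
  while (i <= nrow(ext)) {
    j <- i
    while (j < nrow(ext) && ext$is_max[j + 1L] == ext$is_max[i]) j <- j + 1L
    run <- i:j
    best <- run[which.max(if (ext$is_max[i]) ext$value[run] else -ext$value[run])]
    keep[best] <- TRUE
    i <- j + 1L
  }
  ext <- ext[keep, , drop = FALSE]
  if (any(diff(ext$is_max) == 0))
    stop("non-alternating extrema after pruning")
  ext_peaks <- (ext$idx[ext$is_max] - 1L) / fs
  flex_peaks <- (ext$idx[!ext$is_max] - 1L) / fs
  ext_peaks <- ext_peaks[ext_peaks > t_onset]
  flex_peaks <- flex_peaks[flex_peaks > t_onset]
  if (length(ext_peaks) == 0L || length(flex_peaks) == 0L)
    stop("no movement detected: no post-onset peaks")
  structure(list(t_onset = t_onset,
                 ext_peaks = ext_peaks,
                 flex_peaks = flex_peaks,
                 n_cycles = min(length(ext_peaks), length(flex_peaks)),
                 fs = fs),
            class = "event_table")
}

# Strict local extrema with a two-sided prominence test: each extremum must
# rise (or fall) by at least `min_prom` relative to the lowest (highest)
# level reached before the next opposite extremum on both sides.
find_extrema <- function(x, min_prom) {
  n <- length(x)
  dx <- diff(x)
  sgn <- sign(dx)
  sgn_nz <- sgn
  # carry last nonzero sign through plateaus
  for (i in seq_along(sgn_nz)) if (sgn_nz[i] == 0 && i > 1L)
    sgn_nz[i] <- sgn_nz[i - 1L]
  turns <- which(diff(sgn_nz) != 0) + 1L
  if (length(turns) == 0L)
    return(data.frame(idx = integer(), value = numeric(), is_max = logical()))
  is_max <- sgn_nz[turns - 1L] > 0
  out <- data.frame(idx = turns, value = x[turns], is_max = is_max)
  promin <- vapply(seq_len(nrow(out)), function(k) {
    i <- out$idx[k]
    lo <- if (k == 1L) 1L else out$idx[k - 1L]
    hi <- if (k == nrow(out)) n else out$idx[k + 1L]
    if (out$is_max[k])
      min(out$value[k] - min(x[lo:i]), out$value[k] - min(x[i:hi]))
    else
      min(max(x[lo:i]) - out$value[k], max(x[i:hi]) - out$value[k])
  }, numeric(1))
  out[promin >= min_prom, , drop = FALSE]
}

#' Build direction-tagged half-cycle segments from detected events
#'
#' Extension segment k spans from the preceding flexion peak (movement onset
#' for k = 1) to extension peak k; flexion segment k spans from extension
#' peak k to flexion peak k. Only the first `n_keep` cycles are retained
#' (the final cycle is routinely irregular and dropped).
#'
#' @param events An `event_table` from [detect_events()].
#' @param n_keep Number of complete cycles to keep (default 9).
#' @return A `segment_set` data.frame: `t_start`, `t_end` (s), `direction`,
#'   `cycle_index`.
#' @export
build_segments <- function(events, n_keep = 9) {
  stopifnot(inherits(events, "event_table"))
  n_avail <- events$n_cycles
  if (n_avail < n_keep)
    stop(sprintf("only %d complete cycles detected; %d required",
                 n_avail, n_keep))
  ep <- events$ext_peaks[seq_len(n_keep)]
  fp <- events$flex_peaks[seq_len(n_keep)]
  if (any(fp <= ep))
    stop("events not interleaved: flexion peak precedes its extension peak")
  starts_ext <- c(events$t_onset, fp[-n_keep])
  seg <- data.frame(
    t_start = as.vector(rbind(starts_ext, ep)),
    t_end = as.vector(rbind(ep, fp)),
    direction = rep(c("extension", "flexion"), n_keep),
    cycle_index = rep(seq_len(n_keep), each = 2),
    stringsAsFactors = FALSE
  )
  class(seg) <- c("segment_set", "data.frame")
  seg
}
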