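#' Welch power spectral density of one movement segment
#'
#' 512-point FFT PSD of the high-passed, unrectified sEMG within a movement
#' segment. Segments of at least 512 samples are estimated by Welch
#' averaging (512-sample Hann windows, 50\% overlap); shorter segments use a
#' single zero-padded 512-point window and are flagged. Scaling satisfies
#' Parseval: the sum of `P * df` over all bins equals the window-corrected
#' mean square of the segment.
#'
#' @param x Segment of high-passed sEMG (numeric).
#' @param fs Sampling frequency (Hz, default 1000).
#' @param nfft FFT length (default 512).
#' @param band Analysis band `c(f_min, f_max)` Hz; defaults to 20 Hz (the
#'   hardware high-pass) up to Nyquist.
#' @param provenance Optional named list carried through to the features.
#' @return A `psd_profile`: `f`, `P` (full one-sided grid), `f_band`,
#'   `P_band`, `df`, `band`, `zero_padded`, `n_windows`, `provenance`.
#'   Returns `NULL` with a warning for segments shorter than 64 samples.
#' @export
compute_psd <- function(x, fs = 1000, nfft = 512, band = c(20, fs / 2),
                        provenance = NULL) {
  n <- length(x)
  if (n < 64L) {
    warning(sprintf("segment of %d samples (< 64) skipped", n))
    return(NULL)
  }
  if (all(x == 0)) {
    warning("zero segment skipped (no power)")
    return(NULL)
  }
  zero_padded <- n < nfft
  if (zero_padded) {
    w <- hann_window(n)
    seg <- c(x * w, rep(0, nfft - n))
    scale <- 1 / (fs * sum(w^2))
    pxx <- periodogram_onesided(seg, nfft, scale)
    k <- 1L
  } else {
    step <- nfft %/% 2L
    starts <- seq(1L, n - nfft + 1L, by = step)
    w <- hann_window(nfft)
    scale <- 1 / (fs * sum(w^2))
    acc <- 0
    for (s0 in starts)
      acc <- acc + periodogram_onesided(x[s0:(s0 + nfft - 1L)] * w, nfft, scale)
    pxx <- acc / length(starts)
    k <- length(starts)
  }
  df <- fs / nfft
  f <- (0:(nfft %/% 2L)) * df
  sel <- f >= band[1] & f <= band[2]
  structure(list(f = f, P = pxx, df = df, band = band,
                 f_band = f[sel], P_band = pxx[sel],
                 zero_padded = zero_padded, n_windows = k,
                 provenance = provenance),
            class = "psd_profile")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

# One-sided periodogram of an already-windowed (and padded) nfft vector.
periodogram_onesided <- function(seg, nfft, scale) {
  X <- fft(seg)
  half <- nfft %/% 2L
  p <- (Mod(X[1:(half + 1L)])^2) * scale
  p[2:half] <- 2 * p[2:half]
  p
}

#' Mean frequency of a PSD profile
#'
#' Power-weighted mean frequency over the analysis band:
#' \deqn{MNF = \sum_j f_j P_j / \sum_j P_j.}
#'
#' @param psd A `psd_profile` from [compute_psd()], or any list with
#'   `f_band` and `P_band`.
#' @return Mean frequency (Hz).
#' @export
mnf <- function(psd) {
  P <- psd$P_band
  f <- psd$f_band
  tot <- sum(P)
  if (!is.finite(tot) || tot <= 0) stop("zero total power in band")
  sum(f * P) / tot
}

#' Median frequency of a PSD profile
#'
#' The frequency splitting the band-limited spectrum into two halves of
#' equal power. By default the bin whose cumulative power crosses half the
#' total is linearly interpolated, treating bin j's power as spread over
#' `[f_j - df/2, f_j + df/2]`, which gives sub-bin resolution while keeping
#' the point-mass identity (all power in one bin returns that bin's
#' frequency exactly); `interpolate = FALSE` returns the discrete crossing
#' bin frequency.
#'
#' @inheritParams mnf
#' @param interpolate Interpolate within the crossing bin (default TRUE).
#' @return Median frequency (Hz).
#' @export
mdf <- function(psd, interpolate = TRUE) {
  P <- psd$P_band
  f <- psd$f_band
  tot <- sum(P)
  if (!is.finite(tot) || tot <= 0) stop("zero total power in band")
  cs <- cumsum(P)
  half <- tot / 2
  j <- which(cs >= half)[1L]
  if (!interpolate) return(f[j])
  dfreq <- if (length(f) > 1L) f[2L] - f[1L] else 0
  prev <- if (j == 1L) 0 else cs[j - 1L]
  frac <- (half - prev) / P[j]
  m <- f[j] + (frac - 0.5) * dfreq
  min(max(m, f[1L]), f[length(f)])
}

#' Total band power of a PSD profile
#' @inheritParams mnf
#' @return `sum(P_band) * df` (signal units squared).
#' @export
total_power <- function(psd) sum(psd$P_band) * psd$df

#' Per-segment frequency features and areas for a cohort
#'
#' Runs the full per-recording chain on every recording: 5 Hz angle filter,
#' event detection, half-cycle segmentation (first `n_keep` cycles), 20 Hz
#' EMG high-pass, rectification with pre-onset background subtraction, 10 Hz
#' envelope and integrated area, Welch PSD with MNF/MDF on the unrectified
#' high-passed signal.
#'
#' @param recordings List of `recording` objects (see
#'   [generate_recording()] / [read_recordings()]).
#' @param n_keep Cycles retained per recording (default 9).
#' @param band Spectral analysis band (Hz).
#' @param mdf_interpolate Passed to [mdf()].
#' @param psd_mode `"welch"` (default) or `"single512"` (first 512 samples
#'   of each segment as a single window).
#' @return `data.table` with one row per participant x muscle x direction x
#'   cycle: `participant_id`, `group`, `muscle`, `direction`, `cycle_index`,
#'   `mnf`, `mdf`, `total_power`, `area`, `zero_padded`.
#' @export
features_for_cohort <- function(recordings, n_keep = 9, band = c(20, 500),
                                mdf_interpolate = TRUE,
                                psd_mode = c("welch", "single512")) {
  analyze_cohort(recordings, n_keep = n_keep, band = band,
                 mdf_interpolate = mdf_interpolate,
                 psd_mode = psd_mode)$features
}

#' Full per-recording analysis of a cohort
#'
#' Workhorse behind [features_for_cohort()] and [run_pipeline()]: runs the
#' preprocessing chain and spectral estimation on every recording and keeps
#' the per-segment PSD profiles for the PCA layer.
#'
#' @inheritParams features_for_cohort
#' @return List: `features` (as [features_for_cohort()]), `psds` (named by
#'   `"<muscle>.<direction>"`, each a list with `psds`, `groups`,
#'   `participants`), `events`, `segments` (per-recording tables).
#' @export
analyze_cohort <- function(recordings, n_keep = 9, band = c(20, 500),
                           mdf_interpolate = TRUE,
                           psd_mode = c("welch", "single512")) {
  psd_mode <- match.arg(psd_mode)
  rows <- list()
  psds <- list()
  ev_rows <- list()
  seg_rows <- list()
  for (rec in recordings) {
    fs_a <- rec$angle$fs
    fs_e <- rec$fs_emg
    ang_f <- filter_angle(rec$angle$angle, fs = fs_a)
    ev <- detect_events(ang_f, fs = fs_a)
    seg <- build_segments(ev, n_keep = n_keep)
    ev_rows[[length(ev_rows) + 1L]] <- data.table::data.table(
      participant_id = rec$participant_id, t_onset = ev$t_onset,
      n_ext_peaks = length(ev$ext_peaks), n_flex_peaks = length(ev$flex_peaks))
    seg_rows[[length(seg_rows) + 1L]] <- data.table::data.table(
      participant_id = rec$participant_id, as.data.frame(seg))
    n_valid <- 0L
    for (m in names(rec$emg)) {
      hp <- highpass_emg(rec$emg[[m]], fs = fs_e)
      rd <- rectify_debias(hp, ev$t_onset, fs = fs_e)
      env <- envelope_emg(rd$x, fs = fs_e)
      seg_a <- segment_area(env, seg, fs = fs_e)
      for (i in seq_len(nrow(seg))) {
        i0 <- round(seg$t_start[i] * fs_e) + 1L
        i1 <- min(round(seg$t_end[i] * fs_e) + 1L, length(hp))
        xseg <- hp[i0:i1]
        if (psd_mode == "single512" && length(xseg) > 512L)
          xseg <- xseg[seq_len(512L)]
        psd <- compute_psd(xseg, fs = fs_e, band = band,
                           provenance = list(
                             participant_id = rec$participant_id,
                             muscle = m, direction = seg$direction[i],
                             cycle_index = seg$cycle_index[i]))
        if (is.null(psd)) next
        n_valid <- n_valid + 1L
        key <- paste(m, seg$direction[i], sep = ".")
        if (is.null(psds[[key]]))
          psds[[key]] <- list(psds = list(), groups = character(),
                              participants = character())
        psds[[key]]$psds[[length(psds[[key]]$psds) + 1L]] <- psd
        psds[[key]]$groups <- c(psds[[key]]$groups, rec$group)
        psds[[key]]$participants <- c(psds[[key]]$participants,
                                      rec$participant_id)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          participant_id = rec$participant_id,
          group = rec$group,
          muscle = m,
          direction = seg$direction[i],
          cycle_index = seg$cycle_index[i],
          mnf = mnf(psd),
          mdf = mdf(psd, interpolate = mdf_interpolate),
          total_power = total_power(psd),
          area = seg_a$area[i],
          zero_padded = psd$zero_padded
        )
      }
    }
    if (n_valid == 0L)
      stop("participant ", rec$participant_id, " has no valid segments")
  }
  list(features = data.table::rbindlist(rows),
       psds = psds,
       events = data.table::rbindlist(ev_rows),
       segments = data.table::rbindlist(seg_rows))
}

#' Participant-level means of the cohort feature table
#'
#' Averages cycle-level MNF/MDF/area within participant x muscle x
#' direction; this is the aggregation level at which groups are compared.
#'
#' @param features Output of [features_for_cohort()].
#' @return `data.table` keyed by participant x muscle x direction.
#' @export
participant_means <- function(features) {
  features[, list(mnf = mean(mnf), mdf = mean(mdf), area = mean(area)),
           by = c("participant_id", "group", "muscle", "direction")]
}
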