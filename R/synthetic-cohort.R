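#' Two-pole EMG shaping power spectral density
#'
#' Evaluates the classic unimodal, right-skewed surface-EMG shaping spectrum
#' \deqn{G(f) = g^2 f_h^4 f^2 / ((f^2 + f_l^2)(f^2 + f_h^2)^2)}
#' used by the synthetic generator as the target PSD of the interference
#' signal. It is zero at f = 0, peaks between f_l and f_h, and decays with a
#' wide high-frequency tail, so its band-limited mean frequency exceeds its
#' median frequency.
#'
#' @param f Frequencies (Hz), non-negative.
#' @param params List with `f_low`, `f_high` (Hz, 0 < f_low < f_high < 500)
#'   and `gain` (> 0); see [spectral_shape_params()].
#' @return Power density values (same length as `f`).
#' @export
shaping_psd <- function(f, params) {
  params <- spectral_shape_params(params$f_low, params$f_high, params$gain)
  if (any(f < 0)) stop("frequencies must be non-negative")
  fl2 <- params$f_low^2
  fh2 <- params$f_high^2
  params$gain^2 * fh2^2 * f^2 / ((f^2 + fl2) * (f^2 + fh2)^2)
}

#' @rdname shaping_psd
#' @param f_low,f_high Characteristic low/high frequencies (Hz).
#' @param gain Amplitude scale (arbitrary, mV-like).
#' @export
spectral_shape_params <- function(f_low, f_high, gain = 1) {
  if (!is.numeric(f_low) || !is.numeric(f_high) || !is.numeric(gain) ||
      length(f_low) != 1L || length(f_high) != 1L || length(gain) != 1L ||
      !is.finite(f_low) || !is.finite(f_high) || !is.finite(gain))
    stop("spectral shape parameters must be finite scalars")
  if (!(f_low > 0 && f_low < f_high && f_high < 500))
    stop("require 0 < f_low < f_high < 500 Hz (Nyquist at 1000 Hz sampling)")
  if (gain <= 0) stop("gain must be > 0")
  structure(list(f_low = f_low, f_high = f_high, gain = gain),
            class = "spectral_shape_params")
}

#' Analytic mean and median frequency of the shaping spectrum
#'
#' Ground-truth band-limited spectral moments of [shaping_psd()], computed by
#' adaptive quadrature ([stats::integrate()]) for the mean and by root
#' finding on the cumulative power for the median. These are the continuum
#' analogues of the discrete MNF/MDF estimators and serve as the generator's
#' analytic truth.
#'
#' @param params Spectral shape parameters ([spectral_shape_params()]).
#' @param band Analysis band `c(f1, f2)` in Hz, inside (0, 500].
#' @return List with `mnf` and `mdf` (Hz).
#' @export
analytic_mnf_mdf <- function(params, band = c(20, 500)) {
  if (length(band) != 2L || !all(is.finite(band)) || band[1] >= band[2] ||
      band[1] <= 0 || band[2] > 500)
    stop("`band` must be an increasing pair inside (0, 500] Hz")
  g <- function(f) shaping_psd(f, params)
  fg <- function(f) f * shaping_psd(f, params)
  tot <- integrate(g, band[1], band[2], rel.tol = 1e-10)$value
  if (tot <= 0) stop("zero power in band")
  m1 <- integrate(fg, band[1], band[2], rel.tol = 1e-10)$value
  cdf <- function(x) integrate(g, band[1], x, rel.tol = 1e-10)$value / tot - 0.5
  mdf <- uniroot(cdf, lower = band[1], upper = band[2], tol = 1e-6)$root
  list(mnf = m1 / tot, mdf = mdf)
}

#' Cohort configuration for the synthetic sEMG generator
#'
#' Describes a two-group (COPD vs control) cohort of seated knee
#' flexion-extension trials: 4 sEMG channels at 1000 Hz plus a knee-angle
#' trace at 200 Hz per participant. Control spectral content is set by
#' `control_params`; COPD channels are scaled in frequency so that the
#' analytic band-limited MNF ratio COPD/control equals `mnf_shift_factor`
#' exactly, and in amplitude by `amplitude_ratio`.
#'
#' @param n_per_group Participants per group (>= 2).
#' @param muscles Channel names; extensors RF/VL/VM burst during extension,
#'   BF during flexion.
#' @param control_params Either one `spectral_shape_params` used for every
#'   muscle x direction, or a named list keyed `"<muscle>.<direction>"`.
#' @param mnf_shift_factor Intended COPD/control analytic MNF ratio; scalar
#'   or named like `control_params`.
#' @param amplitude_ratio COPD/control envelope gain (< 1 emulates the
#'   reduced sEMG area in COPD).
#' @param n_cycles Flexion-extension cycles (>= 2; default 10).
#' @param cycle_period Seconds per full cycle.
#' @param baseline_duration Quiet pre-onset baseline (s, >= 0.5).
#' @param angle_range Peak-to-peak knee excursion (degrees).
#' @param angle_noise_sd Goniometer noise SD (degrees; 0 disables).
#' @param background_sd_frac Background white-noise SD as a fraction of the
#'   burst RMS.
#' @param coactivation Antagonist-phase envelope gain relative to agonist.
#' @param rise_fraction Raised-cosine rise/fall fraction of each burst.
#' @param subject_sd_log Log-normal jitter SD applied per participant to
#'   gain and f_high.
#' @param fs_emg,fs_angle_out EMG / angle sampling rates (Hz).
#' @param band Analysis band (Hz) used for the analytic MNF calibration.
#' @param seed Integer master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 10,
                          muscles = MUSCLES,
                          control_params = spectral_shape_params(60, 120, 1),
                          mnf_shift_factor = 1.25,
                          amplitude_ratio = 0.6,
                          n_cycles = 10,
                          cycle_period = 2,
                          baseline_duration = 1,
                          angle_range = 80,
                          angle_noise_sd = 0,
                          background_sd_frac = 0.02,
                          coactivation = 0.05,
                          rise_fraction = 0.1,
                          subject_sd_log = 0.1,
                          fs_emg = 1000,
                          fs_angle_out = 200,
                          band = c(20, 500),
                          seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (n_cycles < 2) stop("n_cycles must be >= 2")
  if (baseline_duration < 0.5) stop("baseline_duration must be >= 0.5 s")
  if (amplitude_ratio <= 0) stop("amplitude_ratio must be > 0")
  if (any(unlist(mnf_shift_factor) <= 0)) stop("mnf_shift_factor must be > 0")
  keys <- as.vector(outer(muscles, DIRECTIONS, paste, sep = "."))
  expand_by_key <- function(x, what) {
    if (inherits(x, "spectral_shape_params") ||
        (is.numeric(x) && length(x) == 1L))
      return(setNames(rep(list(x), length(keys)), keys))
    if (is.list(x) && !is.null(names(x)) && all(keys %in% names(x)))
      return(x[keys])
    if (is.numeric(x) && !is.null(names(x)) && all(keys %in% names(x)))
      return(as.list(x[keys]))
    stop(sprintf("`%s` must be a scalar or named by '<muscle>.<direction>'",
                 what))
  }
  cfg <- structure(list(
    n_per_group = as.integer(n_per_group),
    muscles = muscles,
    control_params = expand_by_key(control_params, "control_params"),
    mnf_shift_factor = expand_by_key(mnf_shift_factor, "mnf_shift_factor"),
    amplitude_ratio = amplitude_ratio,
    n_cycles = as.integer(n_cycles),
    cycle_period = cycle_period,
    baseline_duration = baseline_duration,
    angle_range = angle_range,
    angle_noise_sd = angle_noise_sd,
    background_sd_frac = background_sd_frac,
    coactivation = coactivation,
    rise_fraction = rise_fraction,
    subject_sd_log = subject_sd_log,
    fs_emg = fs_emg,
    fs_angle_out = fs_angle_out,
    band = band,
    seed = as.integer(seed)
  ), class = "cohort_config")
  cfg$copd_params <- lapply(keys, function(k)
    calibrate_shift(cfg$control_params[[k]], cfg$mnf_shift_factor[[k]],
                    band, amplitude_ratio))
  names(cfg$copd_params) <- keys
  cfg
}

# Scale (f_low, f_high) jointly by s so that the band-limited analytic MNF
# ratio shifted/control equals `shift` exactly; error when unattainable
# inside the Nyquist band.
calibrate_shift <- function(params, shift, band, amplitude_ratio) {
  base_mnf <- analytic_mnf_mdf(params, band)$mnf
  target <- shift * base_mnf
  mnf_at <- function(s) {
    p <- spectral_shape_params(params$f_low * s, params$f_high * s,
                               params$gain)
    analytic_mnf_mdf(p, band)$mnf
  }
  s_hi <- min((500 - 1e-6) / params$f_high, 50)
  f <- function(s) mnf_at(s) - target
  lo <- 0.02
  if (f(lo) * f(s_hi) > 0)
    stop(sprintf("requested MNF shift %.3f unattainable within (0, Nyquist)",
                 shift))
  s <- uniroot(f, lower = lo, upper = s_hi, tol = 1e-10)$root
  spectral_shape_params(params$f_low * s, params$f_high * s,
                        params$gain * amplitude_ratio)
}

#' Ground-truth per-group spectral parameters of a cohort configuration
#'
#' @param config A [cohort_config()].
#' @param muscle,direction Channel and movement direction.
#' @param group `"COPD"` or `"control"`.
#' @return The `spectral_shape_params` used (before per-participant jitter).
#' @export
group_shape_params <- function(config, muscle, direction,
                               group = c("control", "COPD")) {
  group <- match.arg(group)
  key <- paste(muscle, direction, sep = ".")
  p <- if (group == "COPD") config$copd_params[[key]]
       else config$control_params[[key]]
  if (is.null(p)) stop("unknown muscle/direction: ", key)
  if (!inherits(p, "spectral_shape_params"))
    p <- spectral_shape_params(p$f_low, p$f_high, p$gain)
  p
}

#' Synthetic knee-angle trace
#'
#' A flat baseline of `baseline_duration` seconds followed by `n_cycles`
#' sinusoidal flexion-extension cycles (raised-cosine half-cycles between
#' alternating extrema). Extension peaks fall at
#' `baseline_duration + T/4 + k T`, flexion minima a half cycle later.
#'
#' @param config A [cohort_config()].
#' @return List with `t` (s), `angle` (degrees, at `fs_angle_out`), and the
#'   ground-truth event times `t_onset`, `ext_peaks`, `flex_peaks`.
#' @export
generate_angle <- function(config) {
  fs <- config$fs_angle_out
  T_cyc <- config$cycle_period
  t_on <- config$baseline_duration
  dur <- t_on + config$n_cycles * T_cyc
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  theta0 <- 90  # resting knee flexion, degrees
  amp <- config$angle_range / 2
  tau <- t - t_on
  angle <- theta0 + ifelse(tau >= 0, amp * sin(2 * pi * tau / T_cyc), 0)
  if (config$angle_noise_sd > 0)
    angle <- angle + rnorm(length(angle), 0, config$angle_noise_sd)
  k <- seq_len(config$n_cycles) - 1L
  list(t = t, angle = angle, fs = fs,
       t_onset = t_on,
       ext_peaks = t_on + T_cyc / 4 + k * T_cyc,
       flex_peaks = t_on + 3 * T_cyc / 4 + k * T_cyc)
}

# Gaussian noise with exactly the target PSD shape: color white noise in the
# frequency domain by sqrt(G) and normalize to unit variance.
shaped_noise <- function(n, fs, params) {
  w <- rnorm(n)
  W <- fft(w)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # fold to [0, fs/2]
  amp <- sqrt(shaping_psd(freqs, params))
  x <- Re(fft(W * amp, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) stop("degenerate shaped noise")
  x / s
}

# Raised-cosine burst envelope over [t0, t1] with rise/fall fraction rf.
burst_envelope <- function(t, t0, t1, rf) {
  u <- (t - t0) / (t1 - t0)
  e <- numeric(length(t))
  inside <- u >= 0 & u <= 1
  ui <- u[inside]
  ei <- rep(1, length(ui))
  ei[ui < rf] <- 0.5 * (1 - cos(pi * ui[ui < rf] / rf))
  ei[ui > 1 - rf] <- 0.5 * (1 - cos(pi * (1 - ui[ui > 1 - rf]) / rf))
  e[inside] <- ei
  e
}

# Deterministic 32-bit seed derived from the master seed and participant id.
derive_seed <- function(seed, participant_id) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(participant_id))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Generate one synthetic recording
#'
#' Builds the knee-angle trace and four sEMG channels for one participant.
#' Each channel is `envelope(t) * shaped_noise(t) + background`, where the
#' envelope bursts over the active half-cycles of that muscle's role
#' (extensors during extension, BF during flexion; antagonist phases at the
#' configured co-activation level) and the shaped noise realizes the group's
#' calibrated spectral parameters, jittered log-normally per participant.
#'
#' @param config A [cohort_config()].
#' @param group `"COPD"` or `"control"`.
#' @param participant_id Identifier string; also seeds the channel noise via
#'   `derive_seed(config$seed, participant_id)`.
#' @return A `recording` object: `participant_id`, `group`, `angle` (list
#'   with `t`, `angle`, `fs`), `emg` (named list of channels at `fs_emg`),
#'   `fs_emg`, `t0_onset_truth`, ground-truth event times and the jittered
#'   per-channel `true_params`.
#' @export
generate_recording <- function(config, group = c("control", "COPD"),
                               participant_id = "P01") {
  group <- match.arg(group)
  pseed <- derive_seed(config$seed, participant_id)
  set.seed(pseed)
  ang <- generate_angle(config)
  fs <- config$fs_emg
  dur <- config$baseline_duration + config$n_cycles * config$cycle_period
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  T_cyc <- config$cycle_period
  t_on <- config$baseline_duration
  kcyc <- seq_len(config$n_cycles) - 1L
  ext_windows <- cbind(c(t_on, ang$flex_peaks[-config$n_cycles]),
                       ang$ext_peaks)
  flex_windows <- cbind(ang$ext_peaks, ang$flex_peaks)
  env_for <- function(windows) {
    e <- numeric(n)
    for (i in seq_len(nrow(windows)))
      e <- e + burst_envelope(t, windows[i, 1], windows[i, 2],
                              config$rise_fraction)
    pmin(e, 1)
  }
  env_ext <- env_for(ext_windows)
  env_flex <- env_for(flex_windows)

  jitter <- exp(rnorm(2 * length(config$muscles), 0, config$subject_sd_log))
  emg <- list()
  true_params <- list()
  for (mi in seq_along(config$muscles)) {
    m <- config$muscles[mi]
    chans <- list()
    for (di in seq_along(DIRECTIONS)) {
      d <- DIRECTIONS[di]
      p0 <- group_shape_params(config, m, d, group)
      jg <- jitter[2 * (mi - 1) + 1]
      jf <- jitter[2 * mi]
      f_high_j <- min(p0$f_high * jf, 499.9)
      p <- spectral_shape_params(p0$f_low, f_high_j, p0$gain * jg)
      true_params[[paste(m, d, sep = ".")]] <- p
      chans[[d]] <- p$gain * shaped_noise(n, fs, p)
    }
    is_ext <- m %in% EXTENSORS
    ago_env <- if (is_ext) env_ext else env_flex
    ant_env <- if (is_ext) env_flex else env_ext
    ago_dir <- if (is_ext) "extension" else "flexion"
    ant <- if (is_ext) "flexion" else "extension"
    sig <- ago_env * chans[[ago_dir]] + config$coactivation * ant_env * chans[[ant]]
    burst_rms <- group_shape_params(config, m, ago_dir, group)$gain
    sig <- sig + rnorm(n, 0, config$background_sd_frac * burst_rms)
    emg[[m]] <- sig
  }
  structure(list(participant_id = participant_id,
                 group = group,
                 angle = ang[c("t", "angle", "fs")],
                 emg = emg,
                 fs_emg = fs,
                 t0_onset_truth = t_on,
                 ext_peaks_truth = ang$ext_peaks,
                 flex_peaks_truth = ang$flex_peaks,
                 true_params = true_params,
                 seed = pseed),
            class = "recording")
}

#' Generate a full two-group cohort
#'
#' @param config A [cohort_config()].
#' @return List of `recording` objects (control then COPD), with participant
#'   ids `C01..` and `P01..`.
#' @export
generate_cohort <- function(config) {
  ids <- c(sprintf("C%02d", seq_len(config$n_per_group)),
           sprintf("P%02d", seq_len(config$n_per_group)))
  groups <- rep(c("control", "COPD"), each = config$n_per_group)
  recs <- mapply(function(id, g) generate_recording(config, g, id),
                 ids, groups, SIMPLIFY = FALSE)
  names(recs) <- ids
  recs
}
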