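#' Second-order Butterworth coefficients
#'
#' Digital biquad coefficients for a 2nd-order Butterworth low- or high-pass
#' filter obtained by bilinear transform with cutoff prewarping.
#'
#' @param cutoff Cutoff frequency in Hz (-3 dB point of a single pass).
#' @param fs Sampling frequency in Hz.
#' @param type `"low"` or `"high"`.
#' @return List with numerator `b` and denominator `a` (length 3, `a[1] = 1`).
#' @export
butter2 <- function(cutoff, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 ||
      cutoff >= fs / 2)
    stop("`cutoff` must lie in (0, fs/2)")
  wc <- tan(pi * cutoff / fs)
  k <- sqrt(2)
  den <- 1 + k * wc + wc^2
  a <- c(1, 2 * (wc^2 - 1) / den, (1 - k * wc + wc^2) / den)
  b <- if (type == "low") {
    c(wc^2, 2 * wc^2, wc^2) / den
  } else {
    c(1, -2, 1) / den
  }
  list(b = b, a = a)
}

# Steady-state initial filter state so that a constant input x produces a
# constant output (scipy lfilter_zi construction).
lfilter_zi <- function(b, a) {
  n <- max(length(b), length(a)) - 1L
  bb <- c(b, rep(0, n + 1L - length(b)))
  aa <- c(a, rep(0, n + 1L - length(a)))
  # companion matrix of aa, transposed
  A <- rbind(-aa[-1L], cbind(diag(1, n - 1L), rep(0, n - 1L)))
  B <- bb[-1L] - aa[-1L] * bb[1L]
  solve(diag(1, n) - t(A), B)
}

#' Zero-phase (forward-backward) Butterworth filtering
#'
#' Applies a 2nd-order Butterworth filter forward and backward so that the
#' net phase response is zero and the magnitude response is applied twice.
#' Edge transients are suppressed by odd-reflection padding and steady-state
#' initial conditions.
#'
#' @param x Numeric signal, uniformly sampled.
#' @param fs Sampling frequency (Hz).
#' @param cutoff Cutoff frequency (Hz) of each pass.
#' @param type `"low"` or `"high"`.
#' @return Filtered signal, same length as `x`.
#' @export
zero_phase_butter <- function(x, fs, cutoff, type = c("low", "high")) {
  type <- match.arg(type)
  coefs <- butter2(cutoff, fs, type)
  filtfilt_ba(coefs$b, coefs$a, x)
}

filtfilt_ba <- function(b, a, x) {
  if (anyNA(x)) stop("input signal contains NA")
  padlen <- 3L * max(length(a), length(b))
  n <- length(x)
  if (n <= padlen)
    stop(sprintf("input too short for zero-phase filtering: %d samples (need > %d)",
                 n, padlen))
  ext <- c(2 * x[1L] - x[(padlen + 1L):2L],
           x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter_cpp(b, a, ext, zi * ext[1L])
  y <- rev(y)
  y <- iir_filter_cpp(b, a, y, zi * y[1L])
  y <- rev(y)
  y[(padlen + 1L):(padlen + n)]
}

# Analytic squared magnitude of a single-pass 2nd-order Butterworth at
# normalized frequency f/fc; the two-pass (zero-phase) gain is this value
# squared. Used by tests as an independent oracle and exported for
# completeness.
#' @rdname butter2
#' @param f Frequency (Hz) at which to evaluate the gain.
#' @param passes Number of filter passes (2 for zero-phase filtering).
#' @export
butter2_gain <- function(f, cutoff, type = c("low", "high"), passes = 2) {
  type <- match.arg(type)
  r <- (f / cutoff)^4
  g1 <- if (type == "low") 1 / (1 + r) else r / (1 + r)
  g1^(passes / 2)
}
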