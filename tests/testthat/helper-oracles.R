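# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths (quadrature by trapezoid grid, median by explicit
# cumulative scan, Pearson by the direct covariance formula) so that each
# check is a genuine dual route.

# Trapezoid-grid quadrature of the two-pole shaping PSD on a 0.01 Hz grid.
oracle_mnf_mdf <- function(f_low, f_high, band = c(20, 500), df = 0.01) {
  f <- seq(band[1], band[2], by = df)
  g <- f_high^4 * f^2 / ((f^2 + f_low^2) * (f^2 + f_high^2)^2)
  w <- diff(f) * (head(g, -1) + tail(g, -1)) / 2
  tot <- sum(w)
  mnf <- sum(diff(f) * (head(f * g, -1) + tail(f * g, -1)) / 2) / tot
  cw <- cumsum(c(0, w))
  j <- which(cw >= tot / 2)[1L]
  mdf <- f[j - 1L] + (tot / 2 - cw[j - 1L]) / (cw[j] - cw[j - 1L]) * df
  list(mnf = mnf, mdf = mdf)
}

# Brute-force cumulative-scan median frequency, written as an explicit
# loop; bin j's mass is treated as spread over f_j +/- df/2.
oracle_mdf_scan <- function(f, P) {
  dfreq <- if (length(f) > 1L) f[2L] - f[1L] else 0
  tot <- 0
  for (p in P) tot <- tot + p
  half <- tot / 2
  acc <- 0
  for (j in seq_along(P)) {
    nxt <- acc + P[j]
    if (nxt >= half) {
      m <- (f[j] - dfreq / 2) + (half - acc) / P[j] * dfreq
      if (m < f[1L]) m <- f[1L]
      if (m > f[length(f)]) m <- f[length(f)]
      return(m)
    }
    acc <- nxt
  }
  f[length(f)]
}

# Direct-formula Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Two-sided permutation p-value for a difference in means.
oracle_perm_p <- function(a, b, n_perm = 10000, seed = 1) {
  set.seed(seed)
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    d <- abs(mean(pool[idx]) - mean(pool[-idx]))
    if (d >= obs - 1e-15) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# Analytic amplitude gain of a zero-phase (two-pass) 2nd-order Butterworth,
# written out directly from |H(f)|^2 = 1/(1+(f/fc)^4) per pass.
oracle_butter2_2pass_gain <- function(f, fc, type) {
  r <- (f / fc)^4
  if (type == "low") 1 / (1 + r) else r / (1 + r)
}

# Wrap a bare spectrum into the psd_profile contract.
make_psd <- function(f, P, df = NULL) {
  if (is.null(df)) df <- if (length(f) > 1L) f[2L] - f[1L] else 1
  structure(list(f = f, P = P, df = df, band = range(f),
                 f_band = f, P_band = P,
                 zero_padded = FALSE, n_windows = 1L, provenance = NULL),
            class = "psd_profile")
}

# Frozen two-template spectral fixture: profiles follow a low-frequency or a
# high-frequency two-pole template with per-row frequency-scale jitter,
# log-normal amplitude variation and chi-square-like multiplicative bin
# noise; COPD rows follow the high template. Analyzed unnormalized so both
# template directions carry row variance.
two_template_fixture <- function(seed, n_per_group = 90) {
  set.seed(seed)
  f <- (11:256) * 1000 / 512
  mk <- function(base, n) lapply(seq_len(n), function(i) {
    s <- exp(rnorm(1, 0, 0.08))
    amp <- exp(rnorm(1, 0, 0.5))
    p <- spectral_shape_params(base[1] * s, base[2] * s)
    P <- amp * shaping_psd(f, p) * rgamma(length(f), shape = 8, rate = 8)
    make_psd(f, P, df = 1000 / 512)
  })
  list(psds = c(mk(c(150, 300), n_per_group), mk(c(40, 70), n_per_group)),
       groups = rep(c("COPD", "control"), each = n_per_group),
       f = f,
       template_lo = shaping_psd(f, spectral_shape_params(40, 70)),
       template_hi = shaping_psd(f, spectral_shape_params(150, 300)))
}

# One default synthetic cohort (n = 10 + 10, seed 42) shared across test
# files; generated lazily and memoized to keep the suite fast.
.shared <- new.env(parent = emptyenv())
shared_cohort <- function() {
  if (is.null(.shared$recs)) {
    .shared$config <- cohort_config(n_per_group = 10, seed = 42)
    .shared$recs <- generate_cohort(.shared$config)
  }
  list(config = .shared$config, recs = .shared$recs)
}
shared_features <- function() {
  if (is.null(.shared$features))
    .shared$features <- features_for_cohort(shared_cohort()$recs)
  .shared$features
}
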