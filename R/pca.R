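#' Build a matrix of normalized PSD profiles for one muscle x direction
#'
#' Rows are individual segment PSDs (both groups pooled), normalized to unit
#' area so that PCA characterizes spectral shape rather than amplitude;
#' columns are the frequency bins of the analysis band.
#'
#' @param psds List of `psd_profile` objects sharing one frequency grid.
#' @param groups Character vector of group labels, one per profile.
#' @param normalize Unit-area normalize rows (default TRUE).
#' @return A `profile_matrix`: `X` (rows = profiles), `col_freqs`, `groups`,
#'   `df`. Zero-power profiles are dropped with a warning.
#' @export
build_profile_matrix <- function(psds, groups, normalize = TRUE) {
  stopifnot(length(psds) == length(groups))
  keep <- vapply(psds, function(p) !is.null(p) && sum(p$P_band) > 0,
                 logical(1))
  if (!all(keep))
    warning(sum(!keep), " zero-power profile(s) excluded")
  psds <- psds[keep]
  groups <- groups[keep]
  if (length(psds) < 4L) stop("need at least 2 profiles per group")
  f0 <- psds[[1L]]$f_band
  X <- t(vapply(psds, function(p) {
    if (!isTRUE(all.equal(p$f_band, f0)))
      stop("profiles on different frequency grids")
    p$P_band
  }, numeric(length(f0))))
  df <- psds[[1L]]$df
  if (normalize) X <- X / (rowSums(X) * df)
  for (g in unique(groups))
    if (sum(groups == g) < 2L) stop("need at least 2 profiles per group")
  structure(list(X = X, col_freqs = f0, groups = groups, df = df,
                 normalized = normalize),
            class = "profile_matrix")
}

#' PCA of spectral profiles with varimax rotation
#'
#' Column-centered PCA of the profile matrix; the smallest set of leading
#' components each explaining at least `min_prop` of the total variance
#' (at least 2, at most `k_max`) is retained and varimax-rotated. The
#' rotation matrix is computed from the eigenvalue-scaled loadings (the
#' standard criterion) and applied to the orthonormal component basis, so
#' the returned components are exactly orthonormal and the retained variance
#' sum is preserved. Each component is sign-flipped so its largest-magnitude
#' element is positive, then components are ordered by decreasing explained
#' variance.
#'
#' @param pm A `profile_matrix` from [build_profile_matrix()].
#' @param k_max Maximum number of retained components (default 4).
#' @param min_prop Minimum per-component variance proportion (default 0.10).
#' @return A `pca_model`: `components` (bins x k, unit norm), `proportions`
#'   (post-rotation variance fractions of total), `proportions_unrotated`,
#'   `k`, `col_freqs`, `center`, `centroids` (component centroid
#'   frequencies), `W` (weighting coefficients of the training profiles).
#' @export
fit_pca_varimax <- function(pm, k_max = 4, min_prop = 0.10) {
  stopifnot(inherits(pm, "profile_matrix"))
  X <- pm$X
  if (nrow(X) < k_max + 1L) stop("need more than k_max profiles")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total_var <- sum(ev)
  if (sum(ev > total_var * 1e-12) < 2L) stop("profile matrix is degenerate (rank < 2)")
  prop <- ev / total_var
  k <- max(2L, sum(prop[seq_len(min(k_max, length(prop)))] >= min_prop))
  k <- min(k, k_max, sum(ev > 0))
  V <- pc$rotation[, seq_len(k), drop = FALSE]
  lam <- ev[seq_len(k)]
  scaled <- V %*% diag(sqrt(lam), k)
  R <- if (k >= 2L) stats::varimax(scaled, normalize = FALSE)$rotmat
       else diag(1, 1)
  comp <- V %*% R
  rot_var <- diag(t(R) %*% diag(lam, k) %*% R)
  # sign convention
  for (j in seq_len(k)) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  ord <- order(rot_var, decreasing = TRUE)
  comp <- comp[, ord, drop = FALSE]
  rot_var <- rot_var[ord]
  centroids <- colSums(pm$col_freqs * comp^2)
  model <- structure(list(components = comp,
                          proportions = rot_var / total_var,
                          proportions_unrotated = prop[seq_len(k)],
                          total_variance = total_var,
                          k = k,
                          col_freqs = pm$col_freqs,
                          center = pc$center,
                          centroids = centroids),
                     class = "pca_model")
  model$W <- weighting_coefficients(pm, model)
  model
}

#' Weighting coefficients of profiles on components
#'
#' Pearson correlation between each original (un-centered, normalized)
#' profile row and each rotated component, computed across frequency bins.
#' Quantifies how strongly each individual spectrum resembles each common
#' profile shape.
#'
#' @param pm A `profile_matrix` (or any matrix-bearing list with `X`).
#' @param model A `pca_model` from [fit_pca_varimax()].
#' @return Matrix `W` (profiles x components) of correlations in [-1, 1];
#'   rows with zero variance are NA with a warning.
#' @export
weighting_coefficients <- function(pm, model) {
  X <- if (is.matrix(pm)) pm else pm$X
  comp <- model$components
  W <- matrix(NA_real_, nrow(X), ncol(comp))
  rv <- apply(X, 1L, var)
  bad <- rv == 0 | !is.finite(rv)
  if (any(bad)) warning(sum(bad), " zero-variance profile row(s) excluded")
  W[!bad, ] <- stats::cor(t(X[!bad, , drop = FALSE]), comp)
  colnames(W) <- paste0("PC", seq_len(ncol(comp)))
  W
}

#' Compare group distributions of weighting coefficients
#'
#' For each retained component, compares the COPD and control distributions
#' of weighting coefficients with a two-sample Student's t-test on
#' Fisher-z-transformed values (variance-stabilizing for correlations).
#' Group means and SDs are reported on the r scale.
#'
#' @param W Weighting-coefficient matrix from [weighting_coefficients()].
#' @param groups Group label per row of `W`.
#' @param copd_label,control_label Labels identifying the two groups.
#' @return `data.frame` shaped like a per-muscle PCA summary: `component`,
#'   `proportion` (NA unless `proportions` given), `mean_r_copd`,
#'   `sd_r_copd`, `mean_r_control`, `sd_r_control`, `t`, `df`, `p`.
#' @param proportions Optional variance proportions to include.
#' @export
compare_group_weights <- function(W, groups, copd_label = "COPD",
                                  control_label = "control",
                                  proportions = NULL) {
  ia <- groups == copd_label
  ib <- groups == control_label
  if (sum(ia) < 2L || sum(ib) < 2L)
    stop("need at least 2 profiles per group")
  k <- ncol(W)
  out <- lapply(seq_len(k), function(j) {
    wa <- W[ia, j]; wb <- W[ib, j]
    wa <- wa[is.finite(wa)]; wb <- wb[is.finite(wb)]
    za <- atanh(pmin(pmax(wa, -1 + 1e-12), 1 - 1e-12))
    zb <- atanh(pmin(pmax(wb, -1 + 1e-12), 1 - 1e-12))
    tt <- two_sample_t(za, zb)
    data.frame(component = paste0("PC", j),
               proportion = if (is.null(proportions)) NA_real_
                            else proportions[j],
               mean_r_copd = mean(wa), sd_r_copd = sd(wa),
               mean_r_control = mean(wb), sd_r_control = sd(wb),
               t = tt$statistic, df = tt$df, p = tt$p)
  })
  do.call(rbind, out)
}
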