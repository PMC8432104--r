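#' Normality and variance-homogeneity gates
#'
#' Shapiro-Wilk normality p-value per group and Levene's test (center =
#' mean) for homogeneity of variance between groups; parametric comparisons
#' are gated on all p > 0.05.
#'
#' @param samples Named list of numeric vectors, one per group.
#' @return List: `shapiro_p` (named), `levene_p`, `pass` (all p > 0.05),
#'   `flags` (character notes for undefined tests).
#' @export
normality_variance_gates <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  flags <- character()
  shapiro_p <- vapply(names(samples), function(nm) {
    x <- samples[[nm]]
    if (length(x) < 3L || sd(x) == 0) {
      flags <<- c(flags, paste0("shapiro undefined for ", nm))
      return(NA_real_)
    }
    shapiro.test(x)$p.value
  }, numeric(1))
  lev <- levene_test(samples)
  if (is.na(lev)) flags <- c(flags, "levene undefined")
  pass <- all(c(shapiro_p, lev) > 0.05, na.rm = FALSE)
  list(shapiro_p = shapiro_p, levene_p = lev,
       pass = isTRUE(pass), flags = flags)
}

# Levene's test with center = mean: one-way ANOVA on absolute deviations
# from the group mean.
levene_test <- function(samples) {
  z <- lapply(samples, function(x) abs(x - mean(x)))
  g <- rep(seq_along(z), lengths(z))
  zz <- unlist(z, use.names = FALSE)
  k <- length(z)
  n <- length(zz)
  zbar <- mean(zz)
  zmeans <- vapply(z, mean, numeric(1))
  ss_b <- sum(lengths(z) * (zmeans - zbar)^2)
  ss_w <- sum((zz - zmeans[g])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ss_w == 0) {
    if (ss_b == 0) return(1)  # identical deviation patterns
    return(NA_real_)
  }
  f <- (ss_b / df1) / (ss_w / df2)
  pf(f, df1, df2, lower.tail = FALSE)
}

#' Two-sample Student's t-test
#'
#' Pooled-variance two-tailed t-test (the study-design default, justified by
#' the Levene gate); Welch's variant behind `pooled = FALSE`.
#'
#' @param a,b Numeric samples.
#' @param pooled Use the pooled-variance statistic (default TRUE).
#' @return List: `statistic` (t), `df`, `p`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(a, b, pooled = TRUE) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per sample")
  if (pooled && var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("zero pooled variance with unequal means")
  }
  tt <- t.test(a, b, var.equal = pooled)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Mixed two-way ANOVA (group x frequency parameter)
#'
#' Mixed-design ANOVA with one between-subject factor (group) and one
#' within-subject factor (e.g. MNF vs MDF). Returns F, p and partial
#' eta-squared for the group, within-factor and interaction effects, each
#' against its proper error stratum (subjects within groups for the between
#' effect; parameter x subjects for the within effects).
#'
#' @param values Numeric matrix, rows = participants, columns = within
#'   levels (balanced, complete).
#' @param groups Group label per row.
#' @return `data.frame` with rows `group`, `within`, `interaction`:
#'   `F`, `df1`, `df2`, `p`, `eta_p2`.
#' @export
mixed_anova_2way <- function(values, groups) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("unbalanced or incomplete within-factor data")
  n <- nrow(values)
  J <- ncol(values)
  g <- as.factor(groups)
  G <- nlevels(g)
  if (n != length(groups)) stop("groups length mismatch")
  if (any(table(g) < 2)) stop("need >= 2 participants per group")
  grand <- mean(values)
  subj_m <- rowMeans(values)
  grp_m <- as.vector(tapply(subj_m, g, mean))
  col_m <- colMeans(values)
  cell_m <- apply(values, 2, function(col) tapply(col, g, mean))  # G x J
  if (G == 1) cell_m <- matrix(cell_m, nrow = 1)
  ng <- as.vector(table(g))

  ss_group <- J * sum(ng * (grp_m - grand)^2)
  ss_subj <- J * sum((subj_m - grp_m[as.integer(g)])^2)
  ss_within_param <- n * sum((col_m - grand)^2)
  inter_dev <- t(cell_m) - outer(col_m, rep(1, G)) -
    outer(rep(1, J), as.vector(grp_m)) + grand     # J x G
  ss_inter <- sum(t(inter_dev)^2 * ng)
  # within-error: y_ij - subj_i - cell(g_i, j) + grp_m(g_i)
  cell_for_rows <- cell_m[as.integer(g), , drop = FALSE]
  err <- values - subj_m - cell_for_rows + grp_m[as.integer(g)]
  ss_err_within <- sum(err^2)

  df_group <- G - 1L
  df_subj <- n - G
  df_param <- J - 1L
  df_inter <- (G - 1L) * (J - 1L)
  df_err_w <- (n - G) * (J - 1L)
  mk <- function(name, ss, df1, ss_e, df2) {
    f <- (ss / df1) / (ss_e / df2)
    data.frame(effect = name, F = f, df1 = df1, df2 = df2,
               p = pf(f, df1, df2, lower.tail = FALSE),
               eta_p2 = ss / (ss + ss_e))
  }
  out <- rbind(mk("group", ss_group, df_group, ss_subj, df_subj),
               mk("within", ss_within_param, df_param, ss_err_within, df_err_w),
               mk("interaction", ss_inter, df_inter, ss_err_within, df_err_w))
  rownames(out) <- out$effect
  out
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject one-way ANOVA over k repeated levels (e.g. the nine
#' movement cycles). The Greenhouse-Geisser epsilon is estimated from the
#' covariance of orthonormalized within-participant contrasts and applied to
#' both degrees of freedom before evaluating p.
#'
#' @param values Numeric matrix, rows = participants, columns = k repeated
#'   levels (complete).
#' @return List: `F`, `df1`, `df2` (uncorrected), `epsilon_gg`,
#'   `df1_gg`, `df2_gg`, `p` (GG-corrected), `p_uncorrected`, `eta_p2`.
#' @export
rm_anova_1way_gg <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells in repeated-measures data")
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2L || k < 2L) stop("need >= 2 participants and >= 2 levels")
  grand <- mean(values)
  subj_m <- rowMeans(values)
  col_m <- colMeans(values)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_err <- sum((values - subj_m - rep(col_m, each = n) + grand)^2)
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  f <- if (ss_err == 0) {
    if (ss_cond == 0) 0 else Inf
  } else (ss_cond / df1) / (ss_err / df2)
  # GG epsilon from orthonormal contrasts
  C <- contrasts_orthonormal(k)
  S <- stats::cov(values %*% t(C))
  lam_tr <- sum(diag(S))
  eps <- if (sum(S^2) == 0) 1 else lam_tr^2 / (df1 * sum(S^2))
  eps <- min(max(eps, 1 / df1), 1)
  p_gg <- if (is.infinite(f)) 0 else
    pf(f, eps * df1, eps * df2, lower.tail = FALSE)
  list(F = f, df1 = df1, df2 = df2, epsilon_gg = eps,
       df1_gg = eps * df1, df2_gg = eps * df2,
       p = p_gg,
       p_uncorrected = if (is.infinite(f)) 0
                       else pf(f, df1, df2, lower.tail = FALSE),
       eta_p2 = if (ss_cond + ss_err == 0) 0 else ss_cond / (ss_cond + ss_err))
}

# (k-1) x k orthonormal contrast matrix (rows orthonormal, orthogonal to 1).
contrasts_orthonormal <- function(k) {
  H <- stats::contr.helmert(k)
  t(apply(H, 2, function(col) col / sqrt(sum(col^2))))
}

#' Severity regressions of frequency features on spirometry
#'
#' Pearson correlation (r, two-tailed p) of participant-level MNF and MDF
#' against FEV1 and FEV1/FVC, per muscle and movement direction — the
#' machine-readable analogue of a feature-vs-severity correlation table.
#'
#' @param feature_means Participant-level feature table (see
#'   [participant_means()]) for the patients.
#' @param clinical `data.frame` with `patient_id`, `FEV1`, `FEV1_FVC`
#'   (percent predicted / percent).
#' @return `data.frame`: `feature`, `muscle`, `direction`, `severity`, `n`,
#'   `r`, `p`; cells with a constant predictor or fewer than 3 pairs are NA
#'   and flagged in the `note` column.
#' @export
severity_regression <- function(feature_means, clinical) {
  stopifnot(all(c("patient_id", "FEV1", "FEV1_FVC") %in% names(clinical)))
  fm <- as.data.frame(feature_means)
  fm <- fm[fm$participant_id %in% clinical$patient_id, , drop = FALSE]
  if (nrow(fm) == 0L) stop("no participants match the clinical records")
  out <- list()
  for (feat in c("mnf", "mdf")) for (m in unique(fm$muscle))
    for (d in unique(fm$direction)) for (sv in c("FEV1", "FEV1_FVC")) {
      sub <- fm[fm$muscle == m & fm$direction == d, ]
      xy <- merge(sub[, c("participant_id", feat)], clinical,
                  by.x = "participant_id", by.y = "patient_id")
      x <- xy[[feat]]
      y <- xy[[sv]]
      cc <- complete.cases(x, y)
      x <- x[cc]; y <- y[cc]
      note <- ""
      if (length(x) < 3L) {
        r <- NA_real_; p <- NA_real_; note <- "fewer than 3 pairs"
      } else if (sd(x) == 0 || sd(y) == 0) {
        r <- NA_real_; p <- NA_real_; note <- "constant variable"
      } else {
        ct <- cor.test(x, y, method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        feature = toupper(feat), muscle = m, direction = d, severity = sv,
        n = length(x), r = r, p = p, note = note)
    }
  do.call(rbind, out)
}
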