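test_that("normality and variance gates behave at their nominal rates", {
  # Shapiro-Wilk type-I error at n = 10 over 500 seeded replicates
  set.seed(21)
  rej <- vapply(1:500, function(i)
    shapiro.test(rnorm(10))$p.value < 0.05, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
  # heavy skew is caught
  set.seed(22)
  hit <- vapply(1:200, function(i)
    shapiro.test(exp(rnorm(50)))$p.value < 0.05, logical(1))
  expect_gte(mean(hit), 0.9)
  # gate plumbing
  set.seed(23)
  g <- normality_variance_gates(list(a = rnorm(10), b = rnorm(10)))
  expect_length(g$shapiro_p, 2)
  expect_true(g$levene_p >= 0 && g$levene_p <= 1)
  x <- rnorm(10)
  expect_equal(spectromyo:::levene_test(list(a = x, b = x)), 1)
  gc <- normality_variance_gates(list(a = rep(1, 5), b = rnorm(5)))
  expect_true(any(grepl("shapiro undefined", gc$flags)))
})

test_that("pooled t-test reproduces the published anthropometric comparisons", {
  tab <- copd_anthropometrics()
  pat <- tab[tab$group == "COPD", ]
  ctl <- tab[tab$group == "control", ]
  expect_equal(two_sample_t(pat$age_y, ctl$age_y)$p, 0.801, tolerance = 0.005 / 0.801)
  expect_equal(two_sample_t(pat$height_cm, ctl$height_cm)$p, 0.851,
               tolerance = 0.005 / 0.851)
  # identical samples
  x <- rnorm(8)
  tt <- two_sample_t(x, x)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)
  expect_error(two_sample_t(rep(1, 5), rep(2, 5)), "zero pooled variance")
})

test_that("mixed two-way ANOVA decomposes effects correctly", {
  # pure within-factor effect: parameter significant, group not
  set.seed(31)
  base <- rnorm(20, 100, 5)
  vals <- cbind(MNF = base + 20, MDF = base)
  g <- rep(c("COPD", "control"), each = 10)
  an <- mixed_anova_2way(vals + rnorm(40, 0, 0.5), g)
  expect_lt(an["within", "p"], 1e-6)
  expect_gt(an["group", "p"], 0.05)
  # eta_p2 identity from F and dfs
  for (e in rownames(an)) {
    f <- an[e, "F"]; d1 <- an[e, "df1"]; d2 <- an[e, "df2"]
    expect_equal(an[e, "eta_p2"], f * d1 / (f * d1 + d2), tolerance = 1e-10)
  }
  # collapsed within factor reduces the group effect to the pooled t-test
  set.seed(32)
  y <- rnorm(20)
  an2 <- mixed_anova_2way(cbind(y, y), g)
  tt <- two_sample_t(y[g == "COPD"], y[g == "control"])
  expect_equal(an2["group", "F"], tt$statistic^2, tolerance = 1e-10)
  expect_equal(an2["group", "p"], tt$p, tolerance = 1e-10)
  expect_error(mixed_anova_2way(cbind(y, NA), g), "unbalanced|incomplete")
})

test_that("repeated-measures ANOVA with Greenhouse-Geisser is calibrated", {
  # no within-subject change: F = 0, p = 1
  set.seed(41)
  v <- matrix(rep(rnorm(8), 9), nrow = 8)
  r0 <- rm_anova_1way_gg(v)
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  # epsilon within theoretical bounds on arbitrary fixtures
  for (seed in 1:25) {
    set.seed(seed)
    m <- matrix(rnorm(9 * 12), 12) +
      matrix(rnorm(12), 12, 9) * matrix(runif(9, 0, 2), 12, 9, byrow = TRUE)
    r <- rm_anova_1way_gg(m)
    expect_gte(r$epsilon_gg, 1 / 8)
    expect_lte(r$epsilon_gg, 1)
    expect_true(r$p >= 0 && r$p <= 1)
  }
  # compound symmetry: only a mild correction on average (n = 30 keeps the
  # estimator's small-sample downward bias from dominating)
  set.seed(43)
  eps <- replicate(200, {
    m <- rnorm(30) + matrix(rnorm(30 * 9), 30)
    rm_anova_1way_gg(m)$epsilon_gg
  })
  expect_gt(mean(eps), 0.7)
  expect_error(rm_anova_1way_gg(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("severity regression reports Pearson r per feature cell", {
  clinical <- copd_clinical()
  # features exactly negatively linear in FEV1: r = -1
  fm <- data.frame(participant_id = clinical$patient_id,
                   group = "COPD", muscle = "RF", direction = "extension",
                   mnf = 200 - 0.8 * clinical$FEV1,
                   mdf = 150 - 0.5 * clinical$FEV1, area = 1)
  out <- severity_regression(fm, clinical)
  row <- out[out$feature == "MNF" & out$severity == "FEV1", ]
  expect_equal(row$r, -1, tolerance = 1e-12)
  expect_lt(row$p, 1e-12)
  # r matches the direct covariance oracle
  set.seed(51)
  fm$mnf <- rnorm(10, 120, 10)
  out2 <- severity_regression(fm, clinical)
  r2 <- out2[out2$feature == "MNF" & out2$severity == "FEV1_FVC", "r"]
  expect_equal(r2, oracle_pearson(fm$mnf, clinical$FEV1_FVC),
               tolerance = 1e-12)
  # constant predictor is flagged, not an error
  fm$mdf <- 100
  out3 <- severity_regression(fm, clinical)
  bad <- out3[out3$feature == "MDF", ]
  expect_true(all(is.na(bad$r)))
  expect_true(all(bad$note == "constant variable"))
  # table shape: feature x muscle x direction x severity
  expect_equal(nrow(out), 2 * 1 * 1 * 2)
})
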